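# End-to-end orchestration: segmentation -> counting -> status calling ->
# divergence -> rate fits (optionally stratified).

#' Default pipeline thresholds
#'
#' The analysis defaults: 185 bp region span cap, 100 bp baseline bins,
#' mean coverage floor of 3 reads per cytosine, 0.99 posterior floor, 40%
#' annotation overlap, 1.5 kb promoters.
#' @return Named list of thresholds.
#' @export
pipeline_defaults <- function() {
  list(max_span = 185L, bin_width = 100L, min_mean_reads_per_c = 3,
       posterior_min = 0.99, min_overlap_frac = 0.4, promoter_width = 1500L)
}

#' Run the full region-level epimutation pipeline
#'
#' Stages, in order: segment the genome per context; aggregate per-cytosine
#' counts into regions; apply the coverage filter; fit the binomial mixture
#' and call U/I/M status with the posterior filter; compute the pedigree
#' divergence table; fit the four inheritance models and compare them.
#' Reruns with identical inputs and config are bit-identical.
#'
#' @param genome Named character vector (or FASTA path).
#' @param counts Count table in the internal dialect (or TSV path).
#' @param ped A [pedigree()] (or pedigree TSV path).
#' @param contexts Contexts to analyse.
#' @param config Threshold list as from [pipeline_defaults()].
#' @param seed Seed for the model fits.
#' @param restarts,n_boot Passed to [fit_model()].
#' @param out_dir Optional directory; when given, regions BED, calls TSV,
#'   divergence TSV, fit JSON and a stage log are written per context.
#' @return Named list per context: `regions`, `retention`
#'   (coverage/posterior/combined fractions), `calls`, `divergence`,
#'   `fits`, `comparison`.
#' @export
run_pipeline <- function(genome, counts, ped, contexts = "CG",
                         config = pipeline_defaults(), seed = 1L,
                         restarts = 10L, n_boot = 0L, out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("counts file not found: ", counts)
    counts <- read_counts_tsv(counts)
  }
  if (is.character(ped)) {
    if (!file.exists(ped)) stop("pedigree file not found: ", ped)
    ped <- read_pedigree_tsv(ped)
  }
  samples <- sequenced_samples(ped)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  out <- list()
  for (ctx in contexts) {
    seg <- segment_genome(genome, ctx, max_span = config$max_span)
    ctx_counts <- counts[counts$context == ctx]
    rc <- aggregate_counts(ctx_counts, seg$regions)
    covmask <- coverage_filter(rc, seg$regions, samples = samples,
                               min_mean_reads_per_c = config$min_mean_reads_per_c)
    if (!any(covmask)) stop("stage coverage_filter: no region passed in ", ctx)
    sub <- structure(list(meth = rc$meth[covmask, samples, drop = FALSE],
                          total = rc$total[covmask, samples, drop = FALSE],
                          region_id = rc$region_id[covmask],
                          samples = samples),
                     class = "region_counts")
    sm <- fit_status_model(sub$meth, sub$total)
    calls <- call_status(sub, sm, posterior_min = config$posterior_min)
    retention <- c(coverage = mean(covmask),
                   posterior = mean(calls$retained),
                   combined = mean(covmask) * mean(calls$retained))
    div <- divergence_table(ped, calls)
    p_u <- observed_proportions(calls)[["U"]]
    fits <- lapply(stats::setNames(.MODEL_KINDS, .MODEL_KINDS), function(k)
      fit_model(div, kind = k, restarts = restarts, seed = seed,
                n_boot = 0L, p_u = p_u))
    if (n_boot > 0L)
      fits$ABneutral <- bootstrap_rates(ped, calls, fits$ABneutral,
                                        n_boot = n_boot, seed = seed)
    cmp <- compare_models(fits)
    if (!is.null(out_dir)) {
      write_regions_bed(seg$regions, file.path(out_dir, paste0("regions_", ctx, ".bed")))
      calls_long <- data.table::data.table(
        region_id = rep(sub$region_id, length(samples)),
        sample = rep(samples, each = length(sub$region_id)),
        status = as.vector(calls$status),
        posterior = as.vector(calls$posterior),
        retained = rep(calls$retained, length(samples)))
      data.table::fwrite(calls_long,
                         file.path(out_dir, paste0("calls_", ctx, ".tsv")),
                         sep = "\t")
      data.table::fwrite(div, file.path(out_dir, paste0("divergence_", ctx, ".tsv")),
                         sep = "\t")
      write_fit_json(fits, cmp, file.path(out_dir, paste0("fits_", ctx, ".json")))
      log <- c(sprintf("context\t%s", ctx),
               sprintf("n_regions\t%d", nrow(seg$regions)),
               sprintf("coverage_retention\t%.6f", retention[["coverage"]]),
               sprintf("posterior_retention\t%.6f", retention[["posterior"]]),
               sprintf("combined_retention\t%.6f", retention[["combined"]]),
               sprintf("selected_model\t%s", cmp$selected))
      writeLines(log, file.path(out_dir, paste0("log_", ctx, ".txt")))
    }
    out[[ctx]] <- list(regions = seg$regions, retention = retention,
                       status_model = sm, calls = calls, divergence = div,
                       fits = fits, comparison = cmp)
  }
  out
}
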