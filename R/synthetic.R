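# Seeded synthetic data: genomes, annotations, pedigrees, methylome
# evolution under the inheritance model, and bisulfite read emission.
# Every generator takes an explicit seed and is fully deterministic under it.

#' Simulate a genome with planted annotation and chromosome zones
#'
#' Random nucleotide sequence with a block layout of gene-like and TE-like
#' features over an intergenic background. Gene blocks can be enriched for
#' CG dinucleotides (`cg_enrich` planted motifs per bp) to mimic the higher
#' CG density of genic sequence; `cg_enrich = 0` gives a pure iid
#' base-composition genome. Each chromosome is partitioned into
#' arm / pericentromere / centromere zones around its middle.
#'
#' @param length Total length per chromosome in bp (>= 1000).
#' @param n_chrom Number of chromosomes.
#' @param seed Integer seed (mandatory).
#' @param base_prob Probabilities of A, C, G, T.
#' @param gene_frac,te_frac Fractions of each chromosome covered by genes
#'   and TEs (alternating blocks with intergenic gaps).
#' @param cg_enrich Planted CG dinucleotides per bp inside gene blocks.
#' @param zone_frac Fractions of the chromosome given to the centromere and
#'   to each flanking pericentromere.
#' @return List: `genome` (named character vector), `annotation`
#'   (data.table chrom/start/end/strand/type/id, 0-based half-open; types
#'   gene, TE, UTR5, UTR3), `zones` (chrom/start/end/zone partition),
#'   `chrom_lengths`.
#' @export
simulate_genome <- function(length = 100000L, n_chrom = 1L, seed,
                            base_prob = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
                            gene_frac = 0.35, te_frac = 0.2, cg_enrich = 0.02,
                            zone_frac = c(centromere = 0.1, pericentromere = 0.15)) {
  if (missing(seed)) stop("seed is mandatory")
  if (length < 1000L) stop("genome length must be at least 1 kb")
  if (abs(sum(base_prob) - 1) > 1e-9 || any(base_prob < 0))
    stop("invalid base composition")
  if (gene_frac + te_frac > 0.9) stop("gene and TE fractions leave no intergenic space")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  bases <- names(base_prob)
  genome <- character(n_chrom)
  ann <- list(); zones <- list()
  for (ci in seq_len(n_chrom)) {
    ch <- paste0("chr", ci)
    b <- sample(bases, length, replace = TRUE, prob = base_prob)
    # alternating gene / TE blocks with intergenic gaps
    n_genes <- max(1L, round(gene_frac * length / 2000L))
    n_tes <- max(1L, round(te_frac * length / 1500L))
    blocks <- data.table::data.table(
      type = rep(c("gene", "TE"), c(n_genes, n_tes)),
      width = c(rep(2000L, n_genes), rep(1500L, n_tes)))
    blocks <- blocks[sample(.N)]
    gap <- max(50L, (length - sum(blocks$width)) %/% (nrow(blocks) + 1L))
    pos <- gap
    blocks[, start := NA_integer_]
    for (k in seq_len(nrow(blocks))) {
      blocks$start[k] <- pos
      pos <- pos + blocks$width[k] + gap
    }
    blocks <- blocks[start + width <= length]
    blocks[, `:=`(end = start + width,
                  strand = sample(c("+", "-"), .N, replace = TRUE),
                  id = sprintf("%s_%s%03d", ch, ifelse(type == "gene", "g", "t"),
                               seq_len(.N)))]
    # plant CG motifs inside gene blocks
    if (cg_enrich > 0) for (k in which(blocks$type == "gene")) {
      n_cg <- stats::rpois(1L, cg_enrich * blocks$width[k])
      if (n_cg > 0L) {
        at <- sample(seq.int(blocks$start[k] + 1L, blocks$end[k] - 1L), n_cg)
        b[at] <- "C"; b[at + 1L] <- "G"
      }
    }
    genome[ci] <- paste(b, collapse = "")
    g <- blocks[type == "gene"]
    utr <- 150L
    ann[[ci]] <- data.table::rbindlist(list(
      blocks[, .(chrom = ch, start, end, strand, type, id)],
      g[, .(chrom = ch,
            start = ifelse(strand == "+", start, end - utr),
            end = ifelse(strand == "+", start + utr, end),
            strand, type = "UTR5", id = paste0(id, "_utr5"))],
      g[, .(chrom = ch,
            start = ifelse(strand == "+", end - utr, start),
            end = ifelse(strand == "+", end, start + utr),
            strand, type = "UTR3", id = paste0(id, "_utr3"))]))
    half_cen <- round(zone_frac[["centromere"]] * length / 2)
    peri <- round(zone_frac[["pericentromere"]] * length)
    mid <- length %/% 2L
    cuts <- c(0L, mid - half_cen - peri, mid - half_cen,
              mid + half_cen, mid + half_cen + peri, length)
    zones[[ci]] <- data.table::data.table(
      chrom = ch, start = cuts[-6L], end = cuts[-1L],
      zone = c("arm", "pericentromere", "centromere", "pericentromere", "arm"))
  }
  names(genome) <- paste0("chr", seq_len(n_chrom))
  list(genome = genome,
       annotation = data.table::rbindlist(ann),
       zones = data.table::rbindlist(zones),
       chrom_lengths = stats::setNames(rep(length, n_chrom), names(genome)))
}

# sampled generations per mutation-accumulation line preset (branch count,
# sequenced generations); MA1_3 and MA2_3 generations spaced evenly over the
# 3..31 range the sequenced material spans
.PED_PRESETS <- list(
  MA1_1 = list(n_branches = 12L, generations = c(3L, 31L, 32L)),
  MA1_2 = list(n_branches = 7L, generations = c(3L, 31L)),
  MA1_3 = list(n_branches = 1L, generations = c(3L, 7L, 10L, 14L, 17L, 21L, 24L, 28L, 31L)),
  MA2_3 = list(n_branches = 2L, generations = c(3L, 10L, 17L, 24L, 31L)))

#' Build a mutation-accumulation pedigree
#'
#' Presets mirror the published single-seed-descent designs: branches
#' radiate from a single founder; along each branch one sibling propagates
#' the line while a second sibling is sequenced at the sampled generations
#' (so every sequenced plant is a leaf hanging off the propagation chain).
#'
#' * `MA1_1`: 12 branches, sequenced at generations 3, 31 and 32.
#' * `MA1_2`: 7 branches, sequenced at generations 3 and 31.
#' * `MA1_3`: a single branch sequenced at nine generations.
#' * `MA2_3`: two branches sequenced at five generations each.
#'
#' @param preset Preset name, or `"custom"` with `nodes` supplied.
#' @param nodes For `preset = "custom"`: a node data.frame for [pedigree()].
#' @return A [pedigree()].
#' @export
build_pedigree <- function(preset = c("MA1_1", "MA1_2", "MA1_3", "MA2_3",
                                      "custom"), nodes = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(nodes)) stop("custom pedigree needs a node table")
    return(pedigree(nodes))
  }
  cfg <- .PED_PRESETS[[preset]]
  gens <- cfg$generations
  rows <- list(data.table::data.table(id = "F", parent = NA_character_,
                                      generation = 0L, sequenced = FALSE))
  for (b in seq_len(cfg$n_branches)) {
    bn <- sprintf("B%02d", b)
    max_prop <- max(gens) - 1L
    prop_id <- function(g) if (g == 0L) "F" else sprintf("%s_P%02d", bn, g)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      id = vapply(seq_len(max_prop), prop_id, character(1L)),
      parent = vapply(seq_len(max_prop) - 1L, prop_id, character(1L)),
      generation = seq_len(max_prop), sequenced = FALSE)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      id = sprintf("%s_S%02d", bn, gens),
      parent = vapply(gens - 1L, prop_id, character(1L)),
      generation = gens, sequenced = TRUE)
  }
  pedigree(data.table::rbindlist(rows))
}

#' Synthetic region scaffold without a genome
#'
#' Regions laid out on pseudo-chromosomes with a fixed number of member
#' cytosines each, for simulations that start at the region level (methylome
#' evolution and read emission without sequence scanning).
#'
#' @param n_regions Number of regions.
#' @param n_c Member cytosines per region (recycled).
#' @param context Context label carried by the regions.
#' @return List with `regions` and `sites` tables (sites carry
#'   `region_idx`).
#' @export
synthetic_regions <- function(n_regions, n_c = 8L, context = "CG") {
  n_c <- rep_len(as.integer(n_c), n_regions)
  span <- pmax(2L * n_c, 2L)
  start <- cumsum(c(0L, span[-n_regions] + 100L))
  regions <- data.table::data.table(
    chrom = "sim1", start = start, end = start + span, context = context,
    n_c = n_c, density = n_c / span,
    region_id = sprintf("%s_sim1_%d", context, start))
  sites <- regions[, .(pos = seq.int(start, by = 2L, length.out = n_c),
                       strand = "+", context = context,
                       region_idx = .GRP),
                   by = region_id]
  sites[, chrom := "sim1"]
  data.table::setcolorder(sites, c("chrom", "pos", "strand", "context",
                                   "region_id", "region_idx"))
  list(regions = regions, sites = sites[])
}

#' Evolve region methylation states along a pedigree
#'
#' Founder states are drawn from the model's founder distribution (its
#' equilibrium by default); each pedigree edge applies one draw from the
#' transition matrix row, independently per region.
#'
#' @param n_regions Number of independent regions.
#' @param ped A [pedigree()].
#' @param model An [inheritance_model()].
#' @param seed Integer seed.
#' @param founder_states Optional explicit integer vector (0/1/2) of founder
#'   states, overriding the equilibrium draw.
#' @return Integer matrix (regions x nodes, colnames = node ids) of states
#'   in {0, 1, 2}.
#' @export
evolve_methylomes <- function(n_regions, ped, model, seed,
                              founder_states = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(founder_states) && is.null(model$pi))
    stop("model has no equilibrium (alpha = 0 or beta = 0); ",
         "supply explicit founder states")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  ord <- order(ped$generation)
  ids <- ped$id[ord]
  parent <- ped$parent[ord]
  states <- matrix(NA_integer_, n_regions, length(ids),
                   dimnames = list(NULL, ids))
  founder <- ids[is.na(parent)]
  states[, founder] <- if (!is.null(founder_states)) {
    stopifnot(length(founder_states) == n_regions)
    as.integer(founder_states)
  } else {
    sample(0:2, n_regions, replace = TRUE, prob = model$pi)
  }
  cum1 <- model$T[, 1L]
  cum2 <- model$T[, 1L] + model$T[, 2L]
  for (k in which(!is.na(parent))) {
    p <- states[, parent[k]] + 1L
    u <- stats::runif(n_regions)
    states[, ids[k]] <- (u > cum1[p]) + (u > cum2[p])
  }
  states
}

#' Emit per-cytosine bisulfite counts from region states
#'
#' For each sequenced sample and each member cytosine: the total read count
#' is drawn from a negative-binomial coverage law and the methylated count
#' from a binomial whose success probability depends on the region's true
#' state (defaults 0.02 / 0.5 / 0.9 for U / I / M, matching the observed
#' region-level methylation distributions; bisulfite non-conversion is
#' subsumed into the U emission).
#'
#' @param states Integer state matrix from [evolve_methylomes()].
#' @param sites Site table with `region_idx` (from [synthetic_regions()] or
#'   [assign_sites()]-derived equivalents).
#' @param samples Sample (node) ids to emit; default all sequenced columns
#'   present in `states`.
#' @param emission Named vector `c(U =, I =, M =)` of per-read methylation
#'   probabilities by state.
#' @param coverage List with `mean` and `size` of the negative-binomial
#'   per-cytosine coverage.
#' @param seed Integer seed.
#' @return Wide count data.table in the pipeline's input dialect (`chrom`,
#'   `pos`, `strand`, `context`, then `meth_*` / `total_*` per sample).
#' @export
emit_counts <- function(states, sites, samples = colnames(states),
                        emission = c(U = 0.02, I = 0.5, M = 0.9),
                        coverage = list(mean = 10, size = 5), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(emission < 0 | emission > 1)) stop("invalid emission probabilities")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  out <- sites[, .(chrom, pos, strand, context)]
  n <- nrow(sites)
  for (s in samples) {
    st <- states[sites$region_idx, s]
    total <- stats::rnbinom(n, size = coverage$size, mu = coverage$mean)
    meth <- stats::rbinom(n, total, emission[st + 1L])
    out[, (paste0("meth_", s)) := meth]
    out[, (paste0("total_", s)) := total]
  }
  out[]
}

#' End-to-end recovery experiment on synthetic data
#'
#' Simulates a pedigree's methylomes under known rates, optionally emits and
#' re-calls read counts through the full aggregation / filtering / mixture
#' pipeline, computes the divergence table and fits the inheritance models,
#' then reports estimation errors against the planted truth.
#'
#' @param n_regions Number of regions.
#' @param preset Pedigree preset for [build_pedigree()].
#' @param alpha,beta,s,kind Planted truth.
#' @param seed Integer seed driving every stage.
#' @param use_reads If `TRUE`, run the read-emission + status-calling path;
#'   if `FALSE`, feed the true states to the divergence stage directly
#'   (perfect status calling).
#' @param fit_kinds Model kinds to fit ("ABneutral" or all four).
#' @param n_c,coverage,emission Region shape and read-emission settings.
#' @param restarts,n_boot Passed to [fit_model()].
#' @return List: `fits`, `comparison` (if all four kinds), `divergence`,
#'   `retention` (filter retention fraction; 1 when `use_reads = FALSE`),
#'   `truth`, `rel_err` (named alpha/beta relative errors for the ABneutral
#'   fit), `ci_covers` (logical alpha/beta, when bootstrapped).
#' @export
end_to_end_recovery <- function(n_regions = 50000L, preset = "MA1_1",
                                alpha = 1.2e-4, beta = 4.6e-4, s = 0,
                                kind = "ABneutral", seed, use_reads = FALSE,
                                fit_kinds = "ABneutral", n_c = 8L,
                                coverage = list(mean = 10, size = 5),
                                emission = c(U = 0.02, I = 0.5, M = 0.9),
                                restarts = 10L, n_boot = 0L) {
  if (missing(seed)) stop("seed is mandatory")
  ped <- build_pedigree(preset)
  model <- inheritance_model(alpha, beta, s, kind)
  scaffold <- synthetic_regions(n_regions, n_c = n_c)
  states <- evolve_methylomes(n_regions, ped, model, seed = seed)
  samples <- sequenced_samples(ped)
  retention <- 1
  if (use_reads) {
    counts <- emit_counts(states, scaffold$sites, samples = samples,
                          emission = emission, coverage = coverage,
                          seed = seed + 1L)
    rc <- aggregate_counts(counts, scaffold$regions)
    covmask <- coverage_filter(rc, scaffold$regions, samples = samples)
    sub <- list(meth = rc$meth[covmask, samples, drop = FALSE],
                total = rc$total[covmask, samples, drop = FALSE],
                region_id = rc$region_id[covmask], samples = samples)
    class(sub) <- "region_counts"
    sm <- fit_status_model(sub$meth, sub$total)
    calls <- call_status(sub, sm)
    retention <- mean(covmask) * mean(calls$retained)
  } else {
    status <- matrix(.STATUS_LEVELS[states[, samples, drop = FALSE] + 1L],
                     n_regions, length(samples),
                     dimnames = list(scaffold$regions$region_id, samples))
    calls <- structure(list(status = status,
                            retained = rep(TRUE, n_regions),
                            region_id = scaffold$regions$region_id,
                            samples = samples),
                       class = "status_calls")
  }
  div <- divergence_table(ped, calls)
  p_u <- observed_proportions(calls)[["U"]]
  fits <- lapply(stats::setNames(fit_kinds, fit_kinds), function(k)
    fit_model(div, kind = k, restarts = restarts, seed = seed + 2L,
              n_boot = 0L, p_u = p_u))
  neutral <- fits[["ABneutral"]] %||% fits[[1L]]
  if (n_boot > 0L)
    neutral <- fits[[neutral$kind]] <- bootstrap_rates(
      ped, calls, neutral, n_boot = n_boot, seed = seed + 3L)
  rel_err <- c(alpha = abs(neutral$estimate[["alpha"]] - alpha) / alpha,
               beta = abs(neutral$estimate[["beta"]] - beta) / beta)
  ci_covers <- if (!is.null(neutral$ci))
    c(alpha = neutral$ci[1L, "alpha"] <= alpha & alpha <= neutral$ci[2L, "alpha"],
      beta = neutral$ci[1L, "beta"] <= beta & beta <= neutral$ci[2L, "beta"])
  else NULL
  list(fits = fits,
       comparison = if (all(.MODEL_KINDS %in% names(fits)))
         compare_models(fits) else NULL,
       divergence = div, retention = retention,
       truth = c(alpha = alpha, beta = beta, s = s),
       rel_err = rel_err, ci_covers = ci_covers)
}
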