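# Annotation-, shape- and chromosome-zone-stratified rate estimation.

.region_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    region_id = regions$region_id)
}

.feature_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = if ("strand" %in% names(features)) features$strand else "*")
}

#' Label regions by overlap with annotation features
#'
#' A region receives a feature's type label when the overlap covers at least
#' `min_overlap_frac` of the region span (region-relative, since regions are
#' the analysis unit). Regions with no feature label are `intergenic`.
#' Multiple labels per region are allowed.
#'
#' @param regions Region table (0-based half-open).
#' @param features data.table with `chrom`, `start`, `end` (0-based
#'   half-open), `type` (e.g. gene, TE, UTR5, UTR3, promoter), optional
#'   `strand` and `id`.
#' @param min_overlap_frac Overlap threshold as a fraction of the region
#'   span (default 0.4).
#' @return data.table `region_id`, `label` (long format; every region
#'   appears at least once, as `intergenic` if nothing else).
#' @export
assign_features <- function(regions, features, min_overlap_frac = 0.4) {
  bad <- setdiff(unique(features$chrom), unique(regions$chrom))
  if (length(bad))
    stop("annotation chromosomes absent from region set: ",
         paste(bad, collapse = ", "))
  rg <- .region_granges(regions)
  fg <- .feature_granges(features)
  hits <- GenomicRanges::findOverlaps(rg, fg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(rg)[qi],
                                           IRanges::ranges(fg)[si]))
  frac <- ow / (regions$end[qi] - regions$start[qi])
  keep <- frac >= min_overlap_frac
  lab <- data.table::data.table(
    region_id = regions$region_id[qi[keep]],
    label = features$type[si[keep]],
    feature_id = if ("id" %in% names(features)) features$id[si[keep]]
                 else NA_character_)
  lab <- unique(lab)
  unlabeled <- setdiff(regions$region_id, lab$region_id)
  data.table::rbindlist(list(
    lab,
    data.table::data.table(region_id = unlabeled, label = "intergenic",
                           feature_id = NA_character_)))
}

#' Promoter intervals upstream of transcription start sites
#'
#' 1.5 kb (by default) upstream of each gene's TSS: `[start-1500, start)` on
#' the plus strand, `[end, end+1500)` on the minus strand, truncated at
#' chromosome bounds.
#'
#' @param genes data.table with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, optional `id`.
#' @param chrom_lengths Named vector of chromosome lengths for truncation
#'   (optional; without it only the 0 bound is applied).
#' @param width Promoter width in bp.
#' @return data.table of promoter intervals with `type = "promoter"`.
#' @export
make_promoters <- function(genes, chrom_lengths = NULL, width = 1500L) {
  start <- ifelse(genes$strand == "+", genes$start - width, genes$end)
  end <- ifelse(genes$strand == "+", genes$start, genes$end + width)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths))
    end <- pmin(end, as.integer(chrom_lengths[genes$chrom]))
  out <- data.table::data.table(
    chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
    strand = genes$strand, type = "promoter",
    id = if ("id" %in% names(genes)) paste0(genes$id, "_prom") else NA_character_)
  out[end > start]
}

#' Split gene-labelled regions into gbM and non-gbM
#'
#' A gene-labelled region becomes `gbM_gene` when it overlaps (at the same
#' threshold used for [assign_features()]) a gene on the gene-body-methylated
#' list, and `non_gbM_gene` when it overlaps a gene not on the list; a
#' region spanning both kinds gets both labels.
#'
#' @param labels Long label table from [assign_features()] (must carry
#'   `feature_id` for gene rows).
#' @param gbm_ids Character vector of gbM gene ids.
#' @return `labels` with `gbM_gene` / `non_gbM_gene` rows appended.
#' @export
split_gbM <- function(labels, gbm_ids) {
  genes <- labels[labels$label == "gene" & !is.na(labels$feature_id)]
  unknown <- setdiff(gbm_ids, labels$feature_id)
  if (length(unknown))
    warning(length(unknown), " gbM id(s) absent from the annotation")
  if (nrow(genes) == 0L) return(labels)
  extra <- data.table::copy(genes)
  extra[, label := ifelse(feature_id %in% gbm_ids, "gbM_gene", "non_gbM_gene")]
  data.table::rbindlist(list(labels, unique(extra)))
}

#' Classify CG regions by size and density
#'
#' Duplets are regions consisting of exactly one strand-symmetric CG dyad
#' (2 Cs spanning 2 bp). Multiplets are classed short/long against the
#' median span and sparse/dense against the median cytosine density; a value
#' equal to the median goes to the lower class (short, sparse).
#'
#' @param regions CG region table.
#' @param density_median,size_median Split points (defaults 0.105 and 104
#'   bp, the genome-wide medians of the reference analysis); set
#'   `recompute = TRUE` to derive both from the data at hand.
#' @param recompute Recompute the medians from `regions`.
#' @return data.table `region_id`, `size_class` (`duplet`,
#'   `multiplet_short`, `multiplet_long`), `density_class` (`dense`,
#'   `sparse`, or NA for duplets).
#' @export
classify_shape <- function(regions, density_median = 0.105, size_median = 104,
                           recompute = FALSE) {
  if (!all(regions$context == "CG")) stop("shape classes are defined for CG regions")
  span <- regions$end - regions$start
  if (recompute) {
    mult <- !(regions$n_c == 2L & span == 2L)
    density_median <- stats::median(regions$density[mult])
    size_median <- stats::median(span[mult])
  }
  duplet <- regions$n_c == 2L & span == 2L
  data.table::data.table(
    region_id = regions$region_id,
    size_class = ifelse(duplet, "duplet",
                        ifelse(span <= size_median, "multiplet_short",
                               "multiplet_long")),
    density_class = ifelse(duplet, NA_character_,
                           ifelse(regions$density > density_median,
                                  "dense", "sparse")))
}

#' Assign regions to chromosome zones by midpoint
#'
#' Zones (arm / pericentromere / centromere) must tile each chromosome; a
#' region belongs to the zone containing its midpoint.
#'
#' @param regions Region table.
#' @param partition data.table with `chrom`, `start`, `end` (0-based
#'   half-open), `zone`.
#' @return Character vector of zones, one per region.
#' @export
assign_zone <- function(regions, partition) {
  missing <- setdiff(unique(regions$chrom), unique(partition$chrom))
  if (length(missing))
    stop("partition missing chromosome(s): ", paste(missing, collapse = ", "))
  mid <- (regions$start + regions$end) %/% 2L
  zone <- rep(NA_character_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    pp <- partition[partition$chrom == ch]
    pp <- pp[order(pp$start)]
    ri <- which(regions$chrom == ch)
    idx <- findInterval(mid[ri], pp$start)
    inside <- idx >= 1L & mid[ri] < pp$end[pmax(idx, 1L)]
    if (any(!inside))
      stop("partition gap on ", ch, " at midpoint(s) ",
           paste(utils::head(mid[ri][!inside], 3L), collapse = ", "))
    zone[ri] <- pp$zone[idx]
  }
  zone
}

#' Stratified divergence and rate estimation
#'
#' For each stratum (a named subset of retained regions), recomputes the
#' divergence table and fits the requested inheritance models. Strata
#' smaller than `min_regions` are reported as unstable (fit skipped with a
#' warning) since few regions yield noisy estimates; empty strata are
#' skipped.
#'
#' @param strata Named list of character vectors of region ids.
#' @param ped A [pedigree()].
#' @param calls `status_calls` object (its retained mask is intersected
#'   with each stratum).
#' @param kinds Model kinds to fit per stratum.
#' @param min_regions Minimum retained regions for a stable fit.
#' @param restarts,seed,n_boot Passed to [fit_model()].
#' @return Named list per stratum: `n_regions`, `divergence`, `fits`
#'   (named list of `rate_fit`), `comparison` (when all four kinds are
#'   fitted), `stable` flag.
#' @export
stratified_rates <- function(strata, ped, calls, kinds = "ABneutral",
                             min_regions = 50L, restarts = 10L, seed = 1L,
                             n_boot = 0L) {
  out <- list()
  for (nm in names(strata)) {
    in_stratum <- calls$region_id %in% strata[[nm]]
    mask <- calls$retained & in_stratum
    if (!any(mask)) {
      warning("stratum '", nm, "' is empty after filtering; skipped")
      next
    }
    stable <- sum(mask) >= min_regions
    if (!stable)
      warning("stratum '", nm, "' has only ", sum(mask),
              " regions; estimates flagged unstable")
    div <- divergence_table(ped, calls, retained = mask)
    fits <- NULL
    if (stable) {
      p_u <- observed_proportions(calls, retained = mask)[["U"]]
      fits <- lapply(stats::setNames(kinds, kinds), function(k)
        fit_model(div, kind = k, restarts = restarts, seed = seed,
                  n_boot = n_boot, p_u = p_u))
    }
    out[[nm]] <- list(
      n_regions = sum(mask), divergence = div, fits = fits,
      comparison = if (!is.null(fits) && all(.MODEL_KINDS %in% names(fits)))
        compare_models(fits) else NULL,
      stable = stable)
  }
  out
}
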