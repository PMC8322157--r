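# Genome segmentation into context-specific cytosine-cluster regions.
#
# Coordinates are 0-based half-open throughout the package; conversion to
# 1-based happens only at TSV import and BED/GFF export.

#' Scan a genome for cytosines of one methylation context
#'
#' Finds every cytosine of the requested trinucleotide context on both
#' strands. A forward-strand C followed by G is CG; by H,G is CHG; by H,H is
#' CHH (H = A, C or T). The reverse strand is assessed on the reverse
#' complement, so a G at position p is a minus-strand C whose context is read
#' leftwards. Ns never match. Cytosines within 2 bp of the 3' chromosome end
#' on their strand are excluded (context undefined); for CG, the mirrored
#' member of a boundary dyad is excluded as well so that every retained CG
#' site has its strand-symmetric partner.
#'
#' @param genome Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return A [data.table::data.table] with columns `chrom`, `pos` (0-based
#'   position of the C on its strand), `strand` (`"+"`/`"-"`), `context`,
#'   sorted by (`chrom`, `pos`).
#' @export
scan_cytosines <- function(genome, context) {
  genome <- .as_sequence_set(genome)
  if (length(genome) == 0L) stop("empty sequence set")
  if (!is.character(context) || length(context) != 1L || !context %in% .CONTEXTS)
    stop("unknown context label: ", paste(context, collapse = ","))
  out <- lapply(names(genome), function(chrom) {
    b <- strsplit(toupper(genome[[chrom]]), "", fixed = TRUE)[[1]]
    n <- length(b)
    if (n < 3L) return(NULL)
    isH <- b %in% .H_BASES            # A, C or T (never N)
    notC_acgt <- b %in% c("A", "G", "T")  # complement is an H base
    # forward: C at 1-based i, context from b[i+1], b[i+2]; keep i <= n-2
    fwd <- which(b == "C")
    fwd <- fwd[fwd <= n - 2L]
    fwd <- switch(context,
      CG  = fwd[b[fwd + 1L] == "G"],
      CHG = fwd[isH[fwd + 1L] & b[fwd + 2L] == "G"],
      CHH = fwd[isH[fwd + 1L] & isH[fwd + 2L]])
    # reverse: minus-strand C is a forward G at i, context from b[i-1], b[i-2]
    rev <- which(b == "G")
    rev <- rev[rev >= 3L]
    rev <- switch(context,
      CG  = rev[b[rev - 1L] == "C"],
      CHG = rev[notC_acgt[rev - 1L] & b[rev - 2L] == "C"],
      CHH = rev[notC_acgt[rev - 1L] & notC_acgt[rev - 2L]])
    if (context == "CG") {
      # keep dyads whole at chromosome boundaries
      fwd <- fwd[fwd != 1L]      # 0-based pos 0: minus partner falls in the
                                 # minus-strand 3' exclusion zone
      rev <- rev[rev != n]       # last position: plus partner excluded above
    }
    if (!length(fwd) && !length(rev)) return(NULL)
    data.table::data.table(
      chrom = chrom,
      pos = c(fwd, rev) - 1L,
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      context = context)
  })
  out <- data.table::rbindlist(out)
  if (nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character()))
  data.table::setorder(out, chrom, pos)
  out[]
}

.as_sequence_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    genome <- as.character(genome)
  }
  if (is.list(genome)) genome <- unlist(genome)
  if (!is.character(genome)) stop("genome must be a named character vector or DNAStringSet")
  if (length(genome) == 0L) stop("empty sequence set")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named")
  if (length(genome) && any(grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", genome)))
    stop("sequences contain non-IUPAC characters")
  as.list(genome)
}

#' Build seed regions from scanned cytosine sites
#'
#' CG: each strand-symmetric dyad (+C at p, -C at p+1) becomes one seed
#' spanning `[p, p+2)`. CHG: each symmetric triad (+C at p, -C at p+2)
#' becomes one seed `[p, p+3)`; CHG sites without a symmetric partner (the
#' CCG/CGG case) become singleton seeds `[p, p+1)`. CHH: every individual
#' site is its own seed `[p, p+1)`. Every input site lands in exactly one
#' seed.
#'
#' @param sites Output of [scan_cytosines()] (single context).
#' @param context Context of the sites.
#' @return data.table of seeds with columns `chrom`, `start`, `end`
#'   (0-based half-open, anchored at member C positions), `context`, `n_c`.
#' @export
build_seeds <- function(sites, context) {
  stopifnot(context %in% .CONTEXTS)
  if (nrow(sites) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  n_c = integer()))
  if (!all(sites$context == context)) stop("sites contain mixed contexts")
  seeds <- lapply(split(sites, sites$chrom), function(ss) {
    plus <- ss$pos[ss$strand == "+"]
    minus <- ss$pos[ss$strand == "-"]
    if (context == "CHH") {
      data.table::data.table(start = ss$pos, end = ss$pos + 1L, n_c = 1L)
    } else if (context == "CG") {
      if (!setequal(plus + 1L, minus))
        stop("CG site lacking its symmetric partner: inconsistent scanning")
      data.table::data.table(start = plus, end = plus + 2L, n_c = 2L)
    } else { # CHG: pair +p with -(p+2) when present, singletons otherwise
      paired_plus <- plus[(plus + 2L) %in% minus]
      paired_minus <- paired_plus + 2L
      lone <- c(setdiff(plus, paired_plus), setdiff(minus, paired_minus))
      data.table::data.table(
        start = c(paired_plus, lone),
        end = c(paired_plus + 3L, lone + 1L),
        n_c = rep(c(2L, 1L), c(length(paired_plus), length(lone))))
    }
  })
  seeds <- data.table::rbindlist(seeds, idcol = "chrom")
  seeds[, `:=`(context = context)]
  data.table::setorder(seeds, chrom, start)
  data.table::setcolorder(seeds, c("chrom", "start", "end", "context", "n_c"))
  seeds[]
}

#' Merge seed regions by iteratively increasing gap distance
#'
#' Implements the cluster-concatenation rule: iterate the inter-cluster gap
#' distance d upward from 0 bp; at each d, scan left to right and merge every
#' adjacent cluster pair whose gap (`next.start - current.end`, the number of
#' bases strictly between the spans) equals d and whose merged span
#' (`next.end - current.start`) does not exceed `max_span`; rescan at the
#' same d until no merge applies, then increment d; stop after
#' `d == max_span`. A pair blocked by the span cap is only skipped — each
#' member may still merge on its other side.
#'
#' @param seeds data.table from [build_seeds()] (any number of chromosomes;
#'   sorted, non-overlapping within a chromosome).
#' @param max_span Maximum merged region span in bp (default 185, the
#'   nucleosome-scale cutoff where methylation autocorrelation collapses).
#' @return data.table of regions with `chrom`, `start`, `end`, `context`,
#'   `n_c`, `density` (`n_c / (end - start)`), `region_id`.
#' @export
merge_regions <- function(seeds, max_span = 185L) {
  if (nrow(seeds) == 0L) {
    out <- data.table::copy(seeds)
    out[, `:=`(density = numeric(), region_id = character())]
    return(out[])
  }
  ctx <- unique(seeds$context)
  if (length(ctx) != 1L) stop("seeds must be a single context")
  merged <- lapply(split(seeds, seeds$chrom), function(ss) {
    s <- ss$start; e <- ss$end; nc <- ss$n_c
    o <- order(s)
    if (is.unsorted(s)) { s <- s[o]; e <- e[o]; nc <- nc[o] }
    if (length(s) > 1L && any(s[-1L] < e[-length(e)]))
      stop("overlapping seeds")
    for (d in 0L:max_span) {
      repeat {
        k <- length(s)
        if (k < 2L) break
        gap <- s[-1L] - e[-k]
        span <- e[-1L] - s[-k]
        cand <- which(gap == d & span <= max_span)
        if (!length(cand)) break
        # left-to-right greedy: a cluster merges at most once per pass
        cand <- cand[c(TRUE, diff(cand) > 1L)]
        e[cand] <- e[cand + 1L]          # ends are increasing: sorted,
        nc[cand] <- nc[cand] + nc[cand + 1L]  # non-overlapping clusters
        drop <- cand + 1L
        s <- s[-drop]; e <- e[-drop]; nc <- nc[-drop]
      }
    }
    data.table::data.table(start = s, end = e, n_c = nc)
  })
  out <- data.table::rbindlist(merged, idcol = "chrom")
  out[, `:=`(context = ctx, density = n_c / (end - start))]
  data.table::setorder(out, chrom, start)
  out[, region_id := sprintf("%s_%s_%d", context, chrom, start)]
  data.table::setcolorder(out, c("chrom", "start", "end", "context", "n_c",
                                 "density", "region_id"))
  out[]
}

#' Segment a genome into cytosine-cluster regions
#'
#' Convenience wrapper: scan, seed and merge in one call.
#'
#' @inheritParams scan_cytosines
#' @inheritParams merge_regions
#' @param chrom_whitelist Optional character vector of chromosome names to
#'   keep (e.g. nuclear chromosomes only, excluding organelles).
#' @return List with elements `sites` (scanned cytosines) and `regions`.
#' @export
segment_genome <- function(genome, context, max_span = 185L,
                           chrom_whitelist = NULL) {
  genome <- .as_sequence_set(genome)
  if (!is.null(chrom_whitelist)) {
    missing <- setdiff(chrom_whitelist, names(genome))
    if (length(missing)) stop("whitelisted chromosomes not in genome: ",
                              paste(missing, collapse = ", "))
    genome <- genome[chrom_whitelist]
  }
  sites <- scan_cytosines(genome, context)
  regions <- merge_regions(build_seeds(sites, context), max_span = max_span)
  list(sites = sites, regions = regions)
}

#' Assign cytosine sites to regions
#'
#' Regions of one context tile their member cytosines without overlap, so a
#' positional interval lookup suffices.
#'
#' @param sites data.table with `chrom`, `pos` (single context).
#' @param regions data.table from [merge_regions()] or [bin_genome()].
#' @return Character vector of `region_id` per site (`NA` if unassigned).
#' @export
assign_sites <- function(sites, regions) {
  ids <- rep(NA_character_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    rr <- regions[regions$chrom == ch]
    si <- which(sites$chrom == ch)
    if (nrow(rr) == 0L || !length(si)) next
    rr <- rr[order(rr$start)]
    idx <- findInterval(sites$pos[si], rr$start)
    ok <- idx >= 1L & sites$pos[si] < rr$end[pmax(idx, 1L)]
    ids[si[ok]] <- rr$region_id[idx[ok]]
  }
  ids
}

#' Partition chromosomes into fixed-width bins
#'
#' Baseline segmentation: non-overlapping bins of `width` bp per chromosome;
#' the final partial bin is retained. If `sites` is supplied, member
#' cytosines are counted per bin (empty bins carry `n_c = 0`).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Bin width in bp (default 100).
#' @param sites Optional single-context site table from [scan_cytosines()].
#' @return data.table of bins shaped like [merge_regions()] output.
#' @export
bin_genome <- function(chrom_lengths, width = 100L, sites = NULL) {
  if (!is.numeric(width) || length(width) != 1L || width < 1L)
    stop("invalid bin width")
  width <- as.integer(width)
  bins <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, len - 1L, by = width)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + width, len))
  })
  bins <- data.table::rbindlist(bins)
  bins[, `:=`(context = if (!is.null(sites) && nrow(sites)) sites$context[1L]
              else NA_character_,
              n_c = 0L)]
  bins[, region_id := sprintf("bin_%s_%d", chrom, start)]
  if (!is.null(sites) && nrow(sites)) {
    ids <- assign_sites(sites, bins)
    cnt <- table(ids)
    bins[match(names(cnt), region_id), n_c := as.integer(cnt)]
  }
  bins[, density := ifelse(n_c > 0L, n_c / (end - start), 0)]
  data.table::setcolorder(bins, c("chrom", "start", "end", "context", "n_c",
                                  "density", "region_id"))
  bins[]
}

#' Methylation autocorrelation over inter-cytosine distance
#'
#' For each distance d in 1..`d_max`, the Pearson correlation of methylation
#' levels over all same-chromosome site pairs exactly d bp apart (strands
#' pooled). The decay of this profile — gradual out to ~185 bp for CG/CHG,
#' then abrupt — motivates the region span cap.
#'
#' @param sites data.table with `chrom`, `pos` and a numeric `level` column
#'   (methylation fraction in `[0, 1]`) for one sample and one context.
#' @param d_max Maximum distance in bp.
#' @return data.table with `distance`, `r` (NA where undefined), `n_pairs`.
#' @export
autocorrelation <- function(sites, d_max) {
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max < 1L)
    stop("d_max must be >= 1")
  if (!"level" %in% names(sites)) stop("sites must carry a 'level' column")
  d_max <- as.integer(d_max)
  by_chrom <- split(sites[, c("pos", "level")], sites$chrom)
  res <- data.table::data.table(distance = seq_len(d_max),
                                r = NA_real_, n_pairs = 0L)
  for (d in seq_len(d_max)) {
    xs <- numeric(0); ys <- numeric(0)
    for (ss in by_chrom) {
      j <- match(ss$pos + d, ss$pos)
      ok <- !is.na(j)
      if (any(ok)) {
        xs <- c(xs, ss$level[ok])
        ys <- c(ys, ss$level[j[ok]])
      }
    }
    n <- length(xs)
    res[d, n_pairs := n]
    if (n >= 2L && stats::sd(xs) > 0 && stats::sd(ys) > 0)
      res[d, r := stats::cor(xs, ys)]
  }
  res[]
}

#' Summary statistics of a region set
#'
#' @param regions data.table from [merge_regions()].
#' @return List with `n_regions`, `median_n_c`, `max_n_c`, `median_density`,
#'   `median_span`, and `frac_le2_c` (fraction of regions with at most two
#'   member cytosines).
#' @export
region_summary <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) stop("empty region list")
  list(
    n_regions = nrow(regions),
    median_n_c = stats::median(regions$n_c),
    max_n_c = max(regions$n_c),
    median_density = stats::median(regions$density),
    median_span = stats::median(regions$end - regions$start),
    frac_le2_c = mean(regions$n_c <= 2L))
}
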