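# Region-level methylation status calling from bisulfite read counts.

#' Aggregate per-cytosine bisulfite counts into regions
#'
#' Sums methylated and total read counts over each region's member cytosines
#' (both strands). Cytosines absent from the count table contribute 0/0;
#' regions with no covered cytosines get 0/0 totals. Count records whose
#' position maps to no region of their context are counted as unassigned
#' with a warning.
#'
#' @param counts data.table with columns `chrom`, `pos` (0-based), `strand`,
#'   `context` and per-sample pairs `meth_<id>`, `total_<id>` (see
#'   [read_counts_tsv()]).
#' @param regions Region table from [merge_regions()] or [bin_genome()]
#'   (single context).
#' @return List of class `region_counts`: integer matrices `meth` and
#'   `total` (regions x samples, dimnames set), `region_id`, `samples`,
#'   `n_unassigned`.
#' @export
aggregate_counts <- function(counts, regions) {
  samples <- .count_samples(counts)
  mcols <- paste0("meth_", samples)
  tcols <- paste0("total_", samples)
  meth <- as.matrix(counts[, mcols, with = FALSE])
  total <- as.matrix(counts[, tcols, with = FALSE])
  if (any(meth > total)) stop("methylated count exceeds total count")
  if (any(meth < 0L) || any(total < 0L)) stop("negative read count")
  ids <- assign_sites(counts, regions)
  n_unassigned <- sum(is.na(ids))
  if (n_unassigned > 0L)
    warning(n_unassigned, " count records map to no region of their context")
  keep <- !is.na(ids)
  f <- factor(ids[keep], levels = regions$region_id)
  msum <- rowsum(meth[keep, , drop = FALSE], f)
  tsum <- rowsum(total[keep, , drop = FALSE], f)
  m <- matrix(0L, nrow(regions), length(samples),
              dimnames = list(regions$region_id, samples))
  t_ <- m
  m[rownames(msum), ] <- as.integer(msum)
  t_[rownames(tsum), ] <- as.integer(tsum)
  structure(list(meth = m, total = t_, region_id = regions$region_id,
                 samples = samples, n_unassigned = n_unassigned),
            class = "region_counts")
}

.count_samples <- function(counts) {
  mcols <- grep("^meth_", names(counts), value = TRUE)
  samples <- sub("^meth_", "", mcols)
  missing <- setdiff(paste0("total_", samples), names(counts))
  if (!length(samples) || length(missing))
    stop("counts must carry meth_<sample>/total_<sample> column pairs")
  samples
}

#' Coverage filter: mean reads per cytosine above a floor in every sample
#'
#' A region passes iff `total / n_c > min_mean_reads_per_c` (strict) for
#' every sequenced sample of the pedigree. Regions with no member cytosines
#' (empty bins) fail automatically.
#'
#' @param counts `region_counts` from [aggregate_counts()].
#' @param regions Region table aligned with `counts$region_id`.
#' @param samples Sample ids that must all pass (default: all columns of
#'   `counts`). An id absent from the count matrix is an error.
#' @param min_mean_reads_per_c Coverage floor (default 3).
#' @return Logical vector, one entry per region.
#' @export
coverage_filter <- function(counts, regions, samples = counts$samples,
                            min_mean_reads_per_c = 3) {
  missing <- setdiff(samples, counts$samples)
  if (length(missing))
    stop("missing sample(s) in count matrix: ", paste(missing, collapse = ", "))
  stopifnot(identical(counts$region_id, regions$region_id))
  n_c <- regions$n_c
  tot <- counts$total[, samples, drop = FALSE]
  pass <- n_c > 0L
  pass[pass] <- apply(tot[pass, , drop = FALSE] / n_c[pass], 1L,
                      function(x) all(x > min_mean_reads_per_c))
  pass
}

#' Fit a three-component binomial mixture to region counts
#'
#' Emission model for status calling: region-level (meth, total) counts are
#' modelled as a mixture of three binomials whose success probabilities
#' correspond to unmethylated, intermediate and methylated regions. Fitted by
#' EM; components are relabelled so that `p_U < p_I < p_M`. If EM degenerates
#' (a mixing weight collapses to zero), the fixed initialization parameters
#' are returned with a warning.
#'
#' @param meth,total Integer vectors (or matrices) of region counts,
#'   restricted to regions passing the coverage filter.
#' @param init_p Initial success probabilities (U, I, M).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return List of class `status_model`: `p` (sorted success probabilities),
#'   `weight`, `loglik`, `n_iter`, `converged`, `degenerate`.
#' @export
fit_status_model <- function(meth, total, init_p = c(0.01, 0.5, 0.95),
                             max_iter = 500L, tol = 1e-8) {
  meth <- as.vector(meth); total <- as.vector(total)
  ok <- total > 0L
  meth <- meth[ok]; total <- total[ok]
  if (length(meth) < 100L)
    stop("need at least 100 region-sample observations with reads")
  p <- init_p
  w <- rep(1 / 3, 3L)
  ll_old <- -Inf
  n_iter <- 0L
  converged <- FALSE
  degenerate <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    lp <- vapply(1:3, function(k)
      log(w[k]) + stats::dbinom(meth, total, p[k], log = TRUE),
      numeric(length(meth)))
    mx <- apply(lp, 1L, max)
    resp <- exp(lp - mx)
    rs <- rowSums(resp)
    ll <- sum(mx + log(rs))
    resp <- resp / rs
    wk <- colSums(resp)
    if (any(wk < 1e-8 * length(meth))) { degenerate <- TRUE; break }
    w <- wk / length(meth)
    p <- pmin(1 - 1e-9, pmax(1e-9, colSums(resp * meth) / colSums(resp * total)))
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    if (n_iter >= max_iter) break
  }
  if (degenerate) {
    warning("EM degenerated (a component weight collapsed); ",
            "falling back to the fixed initialization parameters")
    p <- init_p
    w <- rep(1 / 3, 3L)
    ll <- NA_real_
  }
  o <- order(p)
  structure(list(p = stats::setNames(p[o], .STATUS_LEVELS),
                 weight = stats::setNames(w[o], .STATUS_LEVELS),
                 loglik = ll, n_iter = n_iter, converged = converged,
                 degenerate = degenerate),
            class = "status_model")
}

#' Posterior probabilities of U/I/M for one set of counts
#'
#' Posterior over the three components, proportional to
#' `weight_k * dbinom(meth; total, p_k)`.
#'
#' @param meth,total Numeric vectors of equal length (`total > 0`).
#' @param model `status_model` from [fit_status_model()].
#' @return Numeric matrix (n x 3), rows summing to one, columns U/I/M.
#' @export
status_posterior <- function(meth, total, model) {
  lp <- vapply(1:3, function(k)
    log(model$weight[k]) + stats::dbinom(meth, total, model$p[k], log = TRUE),
    numeric(length(meth)))
  lp <- matrix(lp, ncol = 3L)
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- .STATUS_LEVELS
  post
}

#' Call region methylation status per sample
#'
#' Assigns each region-sample cell the maximum-posterior status (ties broken
#' toward I, the conservative middle state) and retains a region iff the
#' maximum posterior reaches `posterior_min` in every sample.
#'
#' @param counts `region_counts`, already restricted or masked to regions
#'   passing [coverage_filter()] (cells with `total == 0` are an error).
#' @param model `status_model` from [fit_status_model()].
#' @param posterior_min Posterior confidence floor applied across all
#'   samples (default 0.99).
#' @return List of class `status_calls`: character matrix `status`
#'   (U/I/M), numeric matrices `posterior` (max posterior) and `level`
#'   (meth/total), logical `retained` per region, `region_id`, `samples`.
#' @export
call_status <- function(counts, model, posterior_min = 0.99) {
  meth <- counts$meth; total <- counts$total
  if (any(total == 0L))
    stop("call_status received a region-sample cell with no reads; ",
         "apply coverage_filter first")
  post <- status_posterior(as.vector(meth), as.vector(total), model)
  # argmax with ties toward I: bump I by strict comparison order (U, I, M)
  pick <- apply(post, 1L, function(pr) {
    top <- which(pr == max(pr))
    if (length(top) > 1L && 2L %in% top) 2L else top[1L]
  })
  status <- matrix(.STATUS_LEVELS[pick], nrow(meth), ncol(meth),
                   dimnames = dimnames(meth))
  pmax_ <- matrix(post[cbind(seq_along(pick), pick)], nrow(meth), ncol(meth),
                  dimnames = dimnames(meth))
  retained <- apply(pmax_ >= posterior_min, 1L, all)
  structure(list(status = status, posterior = pmax_,
                 level = meth / total, retained = retained,
                 region_id = counts$region_id, samples = counts$samples),
            class = "status_calls")
}

#' Observed U/I/M proportions among retained region calls
#'
#' The genome-wide state proportions anchor the rate fit through the
#' equilibrium assumption (see [fit_model()]'s `p_u`).
#'
#' @param calls `status_calls` from [call_status()], or a character status
#'   matrix.
#' @param retained Optional logical mask (defaults to the mask carried by
#'   `calls`).
#' @return Named numeric vector of proportions (U, I, M) summing to 1.
#' @export
observed_proportions <- function(calls, retained = NULL) {
  status <- if (inherits(calls, "status_calls")) calls$status else calls
  if (is.null(retained))
    retained <- if (inherits(calls, "status_calls")) calls$retained
                else rep(TRUE, nrow(status))
  st <- status[retained, , drop = FALSE]
  tab <- table(factor(st, levels = .STATUS_LEVELS))
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, .STATUS_LEVELS)
}
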