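# Pairwise methylation divergence across a pedigree.

#' Mean methylation divergence between two call vectors
#'
#' Per region, two plants diverge by 1 when one is called M and the other U,
#' by 0.5 when exactly one call is I and they differ, and by 0 when the
#' calls agree. The genome-wide divergence is the mean over the N retained
#' regions.
#'
#' @param calls_i,calls_j Character vectors of U/I/M calls over the same
#'   retained regions, in the same order.
#' @return List with `D` (mean divergence in `[0, 1]`) and `N`.
#' @export
pair_divergence <- function(calls_i, calls_j) {
  if (length(calls_i) != length(calls_j) || !length(calls_i))
    stop("call vectors must be non-empty and of equal length")
  if (anyNA(calls_i) || anyNA(calls_j)) stop("missing call for a retained region")
  d <- .DIV_W[cbind(match(calls_i, .STATUS_LEVELS),
                    match(calls_j, .STATUS_LEVELS))]
  if (anyNA(d)) stop("calls must be U, I or M")
  list(D = mean(d), N = length(d))
}

#' Divergence table over all sequenced pairs of a pedigree
#'
#' One record per unordered pair of sequenced plants: branch lengths to the
#' most recent common ancestor, total divergence time, and observed mean
#' divergence over the retained regions.
#'
#' @param ped A [pedigree()].
#' @param calls A `status_calls` object from [call_status()], or a character
#'   matrix of U/I/M calls (regions x samples).
#' @param retained Logical mask of retained regions; defaults to the mask
#'   carried by `calls` (all regions for a bare matrix).
#' @return data.table with `i`, `j`, `t_i`, `t_j`, `delta_t`, `D`, `N`.
#' @export
divergence_table <- function(ped, calls, retained = NULL) {
  status <- if (inherits(calls, "status_calls")) calls$status else calls
  if (is.null(retained))
    retained <- if (inherits(calls, "status_calls")) calls$retained
                else rep(TRUE, nrow(status))
  samples <- sequenced_samples(ped)
  if (length(samples) < 2L) stop("need at least 2 sequenced samples")
  missing <- setdiff(samples, colnames(status))
  if (length(missing))
    stop("calls missing for sequenced sample(s): ", paste(missing, collapse = ", "))
  status <- status[retained, samples, drop = FALSE]
  pairs <- utils::combn(samples, 2L)
  recs <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    dt <- delta_t(ped, i, j)
    pd <- pair_divergence(status[, i], status[, j])
    data.table::data.table(i = i, j = j, t_i = dt$t_i, t_j = dt$t_j,
                           delta_t = dt$delta_t, D = pd$D, N = pd$N)
  })
  data.table::rbindlist(recs)
}

#' Status-change and stability summary along a time-ordered branch
#'
#' A region counts as changed when both U and M appear among its calls
#' across the sampled generations. It counts as stable when, after the first
#' U-to-M or M-to-U transition, its U/M status never reverts to the original
#' state in any later sampled generation (intermediate calls are ignored for
#' the transition bookkeeping, mirroring the change definition).
#'
#' @param status Character matrix of U/I/M calls, columns ordered by
#'   generation along one branch.
#' @param generations Numeric vector of sampling generations per column,
#'   used only to verify the ordering.
#' @return List with `n_changed` and `fraction_stable` (NA if none changed).
#' @export
status_change_summary <- function(status, generations = NULL) {
  if (!is.null(generations)) {
    if (length(generations) != ncol(status)) stop("generation per column required")
    if (is.unsorted(generations, strictly = TRUE))
      stop("samples must be strictly ordered by generation")
  }
  changed <- logical(nrow(status))
  stable <- logical(nrow(status))
  for (r in seq_len(nrow(status))) {
    um <- status[r, ][status[r, ] %in% c("U", "M")]
    if (length(unique(um)) < 2L) next
    changed[r] <- TRUE
    flip <- which(um[-1L] != um[-length(um)])[1L]
    after <- um[(flip + 1L):length(um)]
    stable[r] <- all(after == um[flip + 1L])
  }
  list(n_changed = sum(changed),
       fraction_stable = if (any(changed)) mean(stable[changed]) else NA_real_)
}
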