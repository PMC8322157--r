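# Selfing Markov inheritance models and epimutation-rate estimation.
#
# State space: k in {0, 1, 2} methylated epialleles at a region in a selfing
# diploid, observed as U (0), I (1), M (2). One generation applies selfing
# segregation S (heterozygotes segregate 1/4 : 1/2 : 1/4, reweighted under
# selection) followed by independent per-allele epimutation E (u -> m with
# probability alpha, m -> u with probability beta).

#' One-generation transition matrix of the selfing inheritance model
#'
#' `T = S(s) %*% E(alpha, beta)`. Segregation S: homozygous states breed
#' true; the heterozygote yields (1/4, 1/2, 1/4), reweighted under selection
#' before renormalization — ABmm weights (1-s, 1-s/2, 1) on (0, 1, 2)
#' (selection against methylation losses), ABuu weights (1, 1-s/2, 1-s)
#' (selection against gains). Epimutation E acts per allele independently,
#' e.g. from k = 0 the row is ((1-a)^2, 2a(1-a), a^2). ABnull is the
#' identity (no accumulation).
#'
#' @param alpha Methylation gain probability per haploid allele per
#'   generation, in `[0, 1]`.
#' @param beta Loss probability per allele per generation, in `[0, 1]`.
#' @param s Selection coefficient in `[0, 1)`; must be 0 for ABneutral.
#' @param kind One of `"ABneutral"`, `"ABmm"`, `"ABuu"`, `"ABnull"`.
#' @return 3x3 row-stochastic matrix over states 0/1/2.
#' @export
transition_matrix <- function(alpha, beta, s = 0, kind = "ABneutral") {
  kind <- match.arg(kind, .MODEL_KINDS)
  if (kind == "ABnull") return(diag(3L))
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  if (s < 0 || s >= 1) stop("s must lie in [0, 1)")
  if (kind == "ABneutral" && s != 0) stop("ABneutral requires s = 0")
  het <- c(0.25, 0.5, 0.25)
  wsel <- switch(kind,
    ABneutral = c(1, 1, 1),
    ABmm = c(1 - s, 1 - s / 2, 1),
    ABuu = c(1, 1 - s / 2, 1 - s))
  het <- het * wsel
  het <- het / sum(het)
  S <- rbind(c(1, 0, 0), het, c(0, 0, 1))
  a <- alpha; b <- beta
  E <- rbind(
    c((1 - a)^2, 2 * a * (1 - a), a^2),
    c(b * (1 - a), (1 - a) * (1 - b) + a * b, a * (1 - b)),
    c(b^2, 2 * b * (1 - b), (1 - b)^2))
  S %*% E
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `T` for eigenvalue 1, normalized to sum 1. Requires
#' an ergodic chain (`alpha > 0` and `beta > 0` make every state reachable).
#'
#' @param T 3x3 row-stochastic matrix.
#' @return Numeric vector `pi` of length 3, `pi %*% T = pi`, `sum(pi) = 1`.
#' @export
equilibrium <- function(T) {
  absorbing <- which(abs(diag(T) - 1) < 1e-15)
  if (length(absorbing))
    stop("chain is not ergodic: absorbing state(s) ",
         paste(absorbing - 1L, collapse = ", "),
         " (alpha = 0 or beta = 0?)")
  e <- eigen(t(T))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

#' Construct an inheritance model object
#'
#' @inheritParams transition_matrix
#' @return List of class `inheritance_model` with `kind`, `alpha`, `beta`,
#'   `s`, `T`, and `pi` (equilibrium; `NULL` for ABnull or non-ergodic
#'   parameters unless `founder` supplies an explicit distribution).
#' @param founder Optional explicit founder state distribution (length 3,
#'   summing to 1) used instead of the equilibrium.
#' @export
inheritance_model <- function(alpha, beta, s = 0, kind = "ABneutral",
                              founder = NULL) {
  Tm <- transition_matrix(alpha, beta, s, kind)
  pi_ <- if (!is.null(founder)) {
    stopifnot(length(founder) == 3L, abs(sum(founder) - 1) < 1e-9)
    founder
  } else if (kind != "ABnull" && alpha > 0 && beta > 0) {
    equilibrium(Tm)
  } else NULL
  structure(list(kind = kind, alpha = alpha, beta = beta, s = s,
                 T = Tm, pi = pi_),
            class = "inheritance_model")
}

# closed-form stationary distribution of T = S(s) %*% E(alpha, beta) with
# heterozygote selection weights w = (w0, w1, w2); obtained by solving
# pi T = pi symbolically, used where eigen() would be too slow
.pi_closed <- function(a, b, w) {
  w0 <- w[1L]; w1 <- w[2L]; w2 <- w[3L]
  den <- -2 * a^3 * w1 - 6 * a^2 * b * w1 + a^2 * w0 + 4 * a^2 * w1 -
    a^2 * w2 - 6 * a * b^2 * w1 + 8 * a * b * w1 + 2 * a * w2 -
    2 * b^3 * w1 - b^2 * w0 + 4 * b^2 * w1 + b^2 * w2 + 2 * b * w0
  p0 <- b * (2 * a^2 * w0 + 2 * a * b * w0 - 2 * a * b * w1 - 4 * a * w0 -
               2 * b^2 * w1 - b * w0 + 4 * b * w1 + b * w2 + 2 * w0) / den
  p2 <- a * (-2 * a^2 * w1 - 2 * a * b * w1 + 2 * a * b * w2 + a * w0 +
               4 * a * w1 - a * w2 + 2 * b^2 * w2 - 4 * b * w2 + 2 * w2) / den
  c(p0, 1 - p0 - p2, p2)
}

.sel_weights <- function(s, kind) {
  switch(kind,
         ABneutral = c(1, 1, 1),
         ABmm = c(1 - s, 1 - s / 2, 1),
         ABuu = c(1, 1 - s / 2, 1 - s))
}

# solve the equilibrium constraint pi_0(alpha, beta, s) = p_u for beta;
# pi_0 is increasing in beta, so bisection on the log scale is safe
.solve_beta <- function(alpha, s, kind, p_u, rate_bounds = c(1e-12, 0.1)) {
  w <- .sel_weights(s, kind)
  f <- function(lb) .pi_closed(alpha, exp(lb), w)[1L] - p_u
  lo <- log(rate_bounds[1L]); hi <- log(min(rate_bounds[2L] * 5, 0.5))
  if (f(lo) >= 0) return(exp(lo))
  if (f(hi) <= 0) return(exp(hi))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-9)$root)
}

# cache of T^0..T^tmax as a list (index t + 1)
.power_chain <- function(Tm, tmax) {
  out <- vector("list", tmax + 1L)
  out[[1L]] <- diag(3L)
  if (tmax >= 1L) out[[2L]] <- Tm
  for (t in seq_len(max(tmax - 1L, 0L)) + 1L) out[[t + 1L]] <- out[[t]] %*% Tm
  out
}

#' Expected methylation divergence between two descendants
#'
#' Two plants descend from a common ancestor (state drawn from the model's
#' founder distribution) through `t_i` and `t_j` independent selfing
#' generations. The expected divergence applies the 1 / 0.5 / 0 weights to
#' the joint state distribution, plus a measurement-noise intercept `c`:
#' `E[D] = c + sum_a pi_a sum_{x,y} (T^t_i)_{a,x} (T^t_j)_{a,y} w(x, y)`.
#' Under ABnull, `E[D] = c`.
#'
#' @param model An [inheritance_model()].
#' @param t_i,t_j Non-negative integer branch lengths (may be vectors of
#'   equal length).
#' @param c_ Intercept (divergence at `t_i = t_j = 0`).
#' @return Numeric vector of expected divergences.
#' @export
expected_divergence <- function(model, t_i, t_j, c_ = 0) {
  if (any(t_i < 0) || any(t_j < 0)) stop("branch lengths must be non-negative")
  if (model$kind == "ABnull") return(rep(c_, length(t_i)))
  if (is.null(model$pi)) stop("model has no founder distribution")
  W <- .DIV_W
  pows <- .power_chain(model$T, max(t_i, t_j))
  vapply(seq_along(t_i), function(k) {
    A <- pows[[t_i[k] + 1L]]
    B <- pows[[t_j[k] + 1L]]
    c_ + sum(model$pi * rowSums((A %*% W) * B))
  }, numeric(1L))
}

#' Fit an inheritance model to a divergence table
#'
#' Minimizes the residual sum of squares between observed pair divergences
#' and [expected_divergence()] over the per-pair branch lengths, by bounded
#' quasi-Newton optimization (rates on the log scale) with multi-start.
#' Standard errors and percentile confidence intervals come from a residual
#' bootstrap. ABnull (`E[D] = c`) is fitted in closed form.
#'
#' The divergence curve alone is exactly invariant under swapping `alpha`
#' and `beta` (relabelling the states 0 and 2 mirrors the equilibrium and
#' leaves the divergence weights unchanged), so gains and losses are only
#' separable through the methylation level of the genome. Supplying `p_u` —
#' the observed proportion of unmethylated region calls — imposes the
#' model's own equilibrium assumption: `beta` is solved from `alpha` (and
#' `s`) so the stationary unmethylated fraction equals `p_u`. Without
#' `p_u`, the unconstrained fit is returned and the (alpha, beta) labelling
#' of the two mirror-equivalent solutions is arbitrary.
#'
#' @param records data.table with columns `t_i`, `t_j`, `D` (from
#'   [divergence_table()]).
#' @param kind Model kind.
#' @param restarts Number of optimization starts (the first uses default
#'   values, the rest draw rates log-uniformly).
#' @param seed Integer seed for the restart draws and bootstrap.
#' @param n_boot Residual-bootstrap replicates for standard errors (0 to
#'   skip).
#' @param p_u Observed unmethylated-region proportion in `(0, 1)`, or
#'   `NULL` for the unconstrained fit.
#' @param init Optional named vector `c(alpha, beta, s, c)` used as a warm
#'   start (replaces the default first start).
#' @param bounds List with elements `rate` (c(lo, hi) for alpha and beta),
#'   `s` and `c_` upper limits.
#' @return List of class `rate_fit`: `kind`, `estimate` (alpha, beta, s,
#'   c), `rss`, `n_obs`, `n_params`, `se`, `ci` (2.5/97.5 percentile),
#'   `converged`, `model`.
#' @export
fit_model <- function(records, kind = "ABneutral", restarts = 20L, seed = 1L,
                      n_boot = 200L, p_u = NULL, init = NULL,
                      bounds = list(rate = c(1e-12, 0.1), s = 0.99, c_ = 1)) {
  kind <- match.arg(kind, .MODEL_KINDS)
  D <- records$D
  n <- length(D)
  if (kind == "ABnull") {
    c_hat <- mean(D)
    return(structure(list(
      kind = kind, estimate = c(alpha = 0, beta = 0, s = 0, c = c_hat),
      rss = sum((D - c_hat)^2), n_obs = n, n_params = 1L,
      se = c(c = stats::sd(D) / sqrt(n)), ci = NULL, converged = TRUE,
      model = inheritance_model(0, 0, 0, "ABnull")), class = "rate_fit"))
  }
  if (n < 4L || length(unique(records$delta_t %||% (records$t_i + records$t_j))) < 2L)
    stop("need at least 4 records with at least 2 distinct divergence times")
  has_s <- kind %in% c("ABmm", "ABuu")
  n_params <- if (has_s) 4L else 3L
  constrained <- !is.null(p_u)
  if (constrained) {
    if (p_u <= 0 || p_u >= 1) stop("p_u must lie strictly in (0, 1)")
    p_u <- min(max(p_u, 1e-6), 1 - 1e-6)
  }
  t_i <- records$t_i; t_j <- records$t_j
  # evaluate E[D] on unique (t_i, t_j) combinations only
  key <- paste(t_i, t_j)
  ukey <- !duplicated(key)
  map <- match(key, key[ukey])
  ut_i <- t_i[ukey]; ut_j <- t_j[ukey]
  # parameter vector: log(alpha) [, log(beta) if unconstrained] [, s] , c
  unpack <- function(par) {
    alpha <- exp(par[1L])
    i <- 2L
    if (constrained) beta <- NA_real_
    else { beta <- exp(par[i]); i <- i + 1L }
    s <- 0
    if (has_s) { s <- par[i]; i <- i + 1L }
    c_ <- par[i]
    if (constrained) beta <- .solve_beta(alpha, s, kind, p_u, bounds$rate)
    list(alpha = alpha, beta = beta, s = s, c_ = c_)
  }
  obj <- function(par) {
    p <- unpack(par)
    m <- inheritance_model(p$alpha, p$beta, p$s, kind)
    ed <- expected_divergence(m, ut_i, ut_j, p$c_)[map]
    sum((D - ed)^2)
  }
  lr <- log(bounds$rate)
  lower <- c(lr[1L], if (!constrained) lr[1L], if (has_s) 0, 0)
  upper <- c(lr[2L], if (!constrained) lr[2L], if (has_s) bounds$s, bounds$c_)
  run_starts <- function(starts) {
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 300L)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    best
  }
  make_starts <- function(k) {
    first <- if (!is.null(init)) {
      c(log(init[["alpha"]]), if (!constrained) log(init[["beta"]]),
        if (has_s) init[["s"]], init[["c"]])
    } else {
      c(log(1e-4), if (!constrained) log(1e-4), if (has_s) 0.1,
        max(min(D), 0))
    }
    first <- pmin(pmax(first, lower), upper)
    c(list(first),
      if (k > 1L) lapply(seq_len(k - 1L), function(dummy) {
        c(stats::runif(if (constrained) 1L else 2L, log(1e-7), log(1e-2)),
          if (has_s) stats::runif(1L, 0, 0.5),
          stats::runif(1L, 0, max(min(D), 1e-3)))
      }))
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  best <- run_starts(make_starts(restarts))
  if (is.null(best))
    stop("no optimization start converged for ", kind,
         " (n = ", n, ", distinct delta_t = ",
         length(unique(t_i + t_j)), ")")
  bp <- unpack(best$par)
  est <- c(alpha = bp$alpha, beta = bp$beta, s = bp$s, c = bp$c_)
  model <- inheritance_model(est[["alpha"]], est[["beta"]], est[["s"]], kind)
  fitted <- expected_divergence(model, ut_i, ut_j, est[["c"]])[map]
  se <- NULL; ci <- NULL
  if (n_boot > 0L) {
    res <- D - fitted
    boot <- matrix(NA_real_, n_boot, 4L,
                   dimnames = list(NULL, c("alpha", "beta", "s", "c")))
    D_full <- D
    for (b in seq_len(n_boot)) {
      # obj closes over D in this environment, so reassigning it rebinds
      # the objective to the resampled responses
      D <- pmin(1, pmax(0, fitted + sample(res, n, replace = TRUE)))
      bf <- run_starts(list(best$par))
      if (!is.null(bf)) {
        bb <- unpack(bf$par)
        boot[b, ] <- c(bb$alpha, bb$beta, bb$s, bb$c_)
      }
    }
    D <- D_full
    se <- apply(boot, 2L, stats::sd, na.rm = TRUE)
    ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  }
  structure(list(kind = kind, estimate = est, rss = best$value, n_obs = n,
                 n_params = n_params, se = se, ci = ci,
                 converged = best$convergence == 0L, model = model),
            class = "rate_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Nested model comparison by F-tests on residual sums of squares
#'
#' Compares ABnull (1 parameter) against ABneutral (3), and ABneutral
#' against each selection model (4), with
#' `F = ((RSS_small - RSS_big) / dp) / (RSS_big / (n - p_big))`.
#' ABneutral is selected unless a selection model improves on it at the 0.05
#' level; ABnull is selected if ABneutral does not improve on ABnull.
#'
#' @param fits Named list with elements `ABneutral`, `ABmm`, `ABuu`,
#'   `ABnull` (all [fit_model()] results on the identical record set).
#' @param alpha_level Significance level for the nested tests.
#' @return List of class `model_comparison`: `selected`, and `tests`
#'   (data.table with comparison, F, df1, df2, p).
#' @export
compare_models <- function(fits, alpha_level = 0.05) {
  need <- .MODEL_KINDS
  if (!all(need %in% names(fits))) stop("fits must contain all four models")
  n <- unique(vapply(fits[need], `[[`, integer(1L), "n_obs"))
  if (length(n) != 1L) stop("fits were made on different record sets")
  ftest <- function(small, big) {
    dp <- big$n_params - small$n_params
    df2 <- n - big$n_params
    Fv <- ((small$rss - big$rss) / dp) / (big$rss / df2)
    Fv <- max(Fv, 0)
    data.table::data.table(
      comparison = paste(small$kind, "vs", big$kind),
      F = Fv, df1 = dp, df2 = df2,
      p = stats::pf(Fv, dp, df2, lower.tail = FALSE))
  }
  tests <- data.table::rbindlist(list(
    ftest(fits$ABnull, fits$ABneutral),
    ftest(fits$ABneutral, fits$ABmm),
    ftest(fits$ABneutral, fits$ABuu)))
  p_neutral <- tests$p[1L]
  p_mm <- tests$p[2L]; p_uu <- tests$p[3L]
  selected <- if (p_neutral >= alpha_level) "ABnull"
  else if (min(p_mm, p_uu) < alpha_level) {
    if (p_mm <= p_uu) "ABmm" else "ABuu"
  } else "ABneutral"
  structure(list(selected = selected, tests = tests), class = "model_comparison")
}

#' Region-level bootstrap confidence intervals for a rate fit
#'
#' Regions are the independent sampling units of the divergence analysis:
#' the pair records of a divergence table all share one realization of the
#' inheritance process, so resampling residuals around the fitted curve
#' misses the replicate-level noise. This bootstrap resamples regions (via
#' their joint status patterns across the sequenced samples), rebuilds every
#' pair divergence and the observed unmethylated proportion from each
#' resample, and refits the model with a warm start at the point estimate.
#'
#' @param ped A [pedigree()].
#' @param calls `status_calls` (or bare status matrix) the original fit was
#'   computed from.
#' @param fit The `rate_fit` to wrap intervals around.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param retained Optional region mask overriding the one in `calls`.
#' @return The `rate_fit` with `se` and `ci` replaced by region-bootstrap
#'   values (percentile 2.5/97.5), plus a `boot` matrix of replicate
#'   estimates.
#' @export
bootstrap_rates <- function(ped, calls, fit, n_boot = 200L, seed = 1L,
                            retained = NULL) {
  status <- if (inherits(calls, "status_calls")) calls$status else calls
  if (is.null(retained))
    retained <- if (inherits(calls, "status_calls")) calls$retained
                else rep(TRUE, nrow(status))
  samples <- sequenced_samples(ped)
  status <- status[retained, samples, drop = FALSE]
  N <- nrow(status)
  # collapse regions to joint status patterns
  pat_key <- do.call(paste0, as.data.frame(status))
  pat <- match(pat_key, unique(pat_key))
  counts <- tabulate(pat)
  upat <- status[!duplicated(pat_key), , drop = FALSE]
  P <- nrow(upat)
  pairs <- utils::combn(samples, 2L)
  K <- ncol(pairs)
  tt <- vapply(seq_len(K), function(k) {
    dt <- delta_t(ped, pairs[1L, k], pairs[2L, k])
    c(dt$t_i, dt$t_j)
  }, numeric(2L))
  # per-pattern divergence contribution to each pair
  ui <- matrix(match(upat, .STATUS_LEVELS), P, length(samples),
               dimnames = dimnames(upat))
  dmat <- vapply(seq_len(K), function(k)
    .DIV_W[cbind(ui[, pairs[1L, k]], ui[, pairs[2L, k]])], numeric(P))
  dmat <- matrix(dmat, nrow = P)
  u_frac <- rowMeans(upat == "U")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 4L,
                 dimnames = list(NULL, c("alpha", "beta", "s", "c")))
  prob <- counts / N
  for (b in seq_len(n_boot)) {
    cnt <- as.vector(stats::rmultinom(1L, N, prob))
    D_star <- as.vector(crossprod(cnt, dmat)) / N
    p_u_star <- sum(cnt * u_frac) / N
    recs <- data.table::data.table(t_i = tt[1L, ], t_j = tt[2L, ], D = D_star)
    bf <- tryCatch(
      fit_model(recs, kind = fit$kind, restarts = 1L, seed = seed + b,
                n_boot = 0L,
                p_u = min(max(p_u_star, 1e-6), 1 - 1e-6),
                init = fit$estimate),
      error = function(e) NULL)
    if (!is.null(bf)) boot[b, ] <- bf$estimate[c("alpha", "beta", "s", "c")]
  }
  fit$se <- apply(boot, 2L, stats::sd, na.rm = TRUE)
  fit$ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
  fit$boot <- boot
  fit
}
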