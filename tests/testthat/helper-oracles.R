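# Independent oracles and fixture builders used across the suite.

# random genome of plain A/C/G/T
random_genome <- function(len, seed, n_chrom = 1L,
                          prob = c(0.3, 0.2, 0.2, 0.3)) {
  set.seed(seed)
  g <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
          collapse = ""), character(1L))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

# brute-force segmentation oracle: repeatedly merge the globally closest
# admissible adjacent pair (smallest gap, leftmost on ties; admissible when
# gap <= max_span and merged span <= max_span)
brute_merge <- function(seeds, max_span = 185L) {
  out <- lapply(split(seeds, seeds$chrom), function(ss) {
    ss <- ss[order(ss$start)]
    s <- ss$start; e <- ss$end; nc <- ss$n_c
    repeat {
      k <- length(s)
      if (k < 2L) break
      gap <- s[-1L] - e[-k]
      span <- e[-1L] - s[-k]
      adm <- which(gap <= max_span & span <= max_span)
      if (!length(adm)) break
      i <- adm[which.min(gap[adm])]
      e[i] <- e[i + 1L]; nc[i] <- nc[i] + nc[i + 1L]
      s <- s[-(i + 1L)]; e <- e[-(i + 1L)]; nc <- nc[-(i + 1L)]
    }
    data.table::data.table(start = s, end = e, n_c = nc)
  })
  data.table::rbindlist(out, idcol = "chrom")
}

# forward Monte-Carlo simulation of paired descendants: the oracle for
# expected_divergence (per-locus simulation of the one-step chain)
simulate_divergence_mc <- function(alpha, beta, t_i, t_j, n, seed,
                                   s = 0, kind = "ABneutral") {
  Tm <- transition_matrix(alpha, beta, s, kind)
  pi_ <- equilibrium(Tm)
  cum1 <- Tm[, 1L]; cum2 <- Tm[, 1L] + Tm[, 2L]
  step_gens <- function(st, t) {
    for (g in seq_len(t)) {
      u <- stats::runif(length(st))
      st <- (u > cum1[st + 1L]) + (u > cum2[st + 1L])
    }
    st
  }
  set.seed(seed)
  anc <- sample(0:2, n, replace = TRUE, prob = pi_)
  x <- step_gens(anc, t_i)
  y <- step_gens(anc, t_j)
  W <- matrix(c(0, 0.5, 1, 0.5, 0, 0.5, 1, 0.5, 0), 3L, 3L)
  d <- W[cbind(x + 1L, y + 1L)]
  list(mean = mean(d), se = stats::sd(d) / sqrt(n))
}

# divergence records over all sequenced pairs with D from the exact curve
exact_divergence_records <- function(ped, model, c_ = 0) {
  pairs <- utils::combn(sequenced_samples(ped), 2L)
  recs <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    dt <- delta_t(ped, pairs[1L, k], pairs[2L, k])
    data.table::data.table(t_i = dt$t_i, t_j = dt$t_j, delta_t = dt$delta_t)
  }))
  recs$D <- expected_divergence(model, recs$t_i, recs$t_j, c_)
  recs
}

# status_calls object straight from true simulated states (perfect calling)
calls_from_states <- function(states, samples) {
  status <- matrix(c("U", "I", "M")[states[, samples, drop = FALSE] + 1L],
                   nrow(states), length(samples),
                   dimnames = list(sprintf("r%06d", seq_len(nrow(states))),
                                   samples))
  structure(list(status = status, retained = rep(TRUE, nrow(states)),
                 region_id = rownames(status), samples = samples),
            class = "status_calls")
}

# fixed three-component model for posterior oracle tests
fixed_status_model <- function(p = c(0.01, 0.5, 0.95)) {
  structure(list(p = stats::setNames(p, c("U", "I", "M")),
                 weight = stats::setNames(rep(1 / 3, 3L), c("U", "I", "M")),
                 loglik = NA_real_, n_iter = 0L, converged = TRUE,
                 degenerate = FALSE),
            class = "status_model")
}
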