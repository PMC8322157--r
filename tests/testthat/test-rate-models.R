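test_that("transition matrix combines segregation and per-allele epimutation", {
  T0 <- transition_matrix(0, 0, 0)
  expect_equal(T0[2L, ], c(0.25, 0.5, 0.25))
  expect_equal(T0[1L, ], c(1, 0, 0))
  expect_equal(T0[3L, ], c(0, 0, 1))

  expect_equal(transition_matrix(1, 0, 0)[1L, ], c(0, 0, 1))
  expect_equal(transition_matrix(0.1, 0.2, 0)[1L, ], c(0.81, 0.18, 0.01))
  # heterozygote epimutation row: beta(1-alpha), (1-a)(1-b)+ab, alpha(1-beta)
  Tm <- transition_matrix(0.1, 0.2, 0)
  het <- c(0.25, 0.5, 0.25) %*% rbind(
    c(0.81, 0.18, 0.01),
    c(0.2 * 0.9, 0.9 * 0.8 + 0.1 * 0.2, 0.1 * 0.8),
    c(0.04, 0.32, 0.64))
  expect_equal(Tm[2L, ], as.vector(het))

  expect_true(all(abs(rowSums(transition_matrix(0.3, 0.1, 0.5, "ABmm")) - 1) < 1e-12))
  expect_equal(transition_matrix(0.1, 0.1, 0, "ABnull"), diag(3L))
  expect_error(transition_matrix(-0.1, 0.2), "alpha")
  expect_error(transition_matrix(0.1, 0.2, s = 1), "s must")
  expect_error(transition_matrix(0.1, 0.2, s = 0.3, kind = "ABneutral"),
               "requires s = 0")
})

test_that("equilibrium matches a power-iteration oracle and detects absorption", {
  Tm <- transition_matrix(0.3, 0.3, 0)
  pi_ <- equilibrium(Tm)
  expect_equal(pi_[1L], pi_[3L], tolerance = 1e-12)
  P <- diag(3L)
  for (k in 1:10000) P <- P %*% Tm
  expect_equal(pi_, P[1L, ], tolerance = 1e-10)
  expect_equal(sum(pi_), 1, tolerance = 1e-12)
  expect_equal(as.vector(pi_ %*% Tm), pi_, tolerance = 1e-12)

  expect_error(equilibrium(transition_matrix(0, 3e-4, 0)), "absorbing")
  # closed-form stationary distribution agrees with the eigen route
  for (kind in c("ABneutral", "ABmm", "ABuu")) {
    s <- if (kind == "ABneutral") 0 else 0.35
    Tk <- transition_matrix(2e-3, 8e-3, s, kind)
    expect_equal(epirate:::.pi_closed(2e-3, 8e-3, epirate:::.sel_weights(s, kind)),
                 equilibrium(Tk), tolerance = 1e-12)
  }
})

test_that("expected divergence matches forward Monte-Carlo simulation", {
  model <- inheritance_model(1e-3, 3e-3)
  mc <- simulate_divergence_mc(1e-3, 3e-3, t_i = 8L, t_j = 8L, n = 2e5,
                               seed = 17)
  ed <- expected_divergence(model, 8L, 8L)
  expect_lt(abs(ed - mc$mean), 3 * mc$se)

  # asymmetric branch lengths
  mc2 <- simulate_divergence_mc(1e-3, 3e-3, t_i = 2L, t_j = 14L, n = 2e5,
                                seed = 18)
  expect_lt(abs(expected_divergence(model, 2L, 14L) - mc2$mean), 3 * mc2$se)

  expect_equal(expected_divergence(model, 0L, 0L, 0.05), 0.05)
  null <- inheritance_model(0, 0, 0, "ABnull")
  expect_equal(expected_divergence(null, c(1L, 20L), c(1L, 20L), 0.07),
               c(0.07, 0.07))
  expect_error(expected_divergence(model, -1L, 2L), "non-negative")
})

test_that("expected divergence is monotone in time and saturates at equilibrium mixing", {
  for (ab in list(c(1e-4, 4e-4), c(1e-3, 1e-3), c(5e-3, 2e-3))) {
    m <- inheritance_model(ab[1L], ab[2L])
    ed <- expected_divergence(m, 0:40, 0:40)
    expect_true(all(diff(ed) > -1e-12))
  }
  m <- inheritance_model(2e-3, 6e-3)
  W <- matrix(c(0, 0.5, 1, 0.5, 0, 0.5, 1, 0.5, 0), 3L, 3L)
  saturation <- as.numeric(m$pi %*% W %*% m$pi)
  expect_equal(expected_divergence(m, 3000L, 3000L), saturation,
               tolerance = 1e-6)
})

test_that("a larger loss-to-gain ratio lowers the methylated fraction", {
  alpha <- 2e-4
  pi2 <- vapply(c(0.5, 1, 2, 5, 10, 50),
                function(r) inheritance_model(alpha, r * alpha)$pi[3L],
                numeric(1L))
  expect_true(all(diff(pi2) < 0))
})

test_that("fitting recovers exact-curve parameters and the flat-data closed form", {
  ped <- build_pedigree("MA1_1")
  truth <- inheritance_model(2e-4, 6e-4)
  recs <- exact_divergence_records(ped, truth, c_ = 0.05)
  fit <- fit_model(recs, "ABneutral", restarts = 10L, seed = 1L, n_boot = 0L,
                   p_u = truth$pi[1L])
  expect_lt(abs(fit$estimate[["alpha"]] - 2e-4) / 2e-4, 0.01)
  expect_lt(abs(fit$estimate[["beta"]] - 6e-4) / 6e-4, 0.01)
  expect_lt(abs(fit$estimate[["c"]] - 0.05), 1e-3)

  flat <- data.table::data.table(t_i = 1:6, t_j = 1:6, D = 0.07)
  nf <- fit_model(flat, "ABnull")
  expect_equal(nf$estimate[["c"]], 0.07)
  expect_equal(nf$rss, 0)

  expect_error(fit_model(flat[1:2], "ABneutral"), "at least 4")
})

test_that("without a proportion anchor the two mirror solutions tie", {
  ped <- build_pedigree("MA1_2")
  truth <- inheritance_model(2e-4, 6e-4)
  recs <- exact_divergence_records(ped, truth, c_ = 0.02)
  mirror <- inheritance_model(6e-4, 2e-4)
  expect_equal(expected_divergence(truth, recs$t_i, recs$t_j, 0.02),
               expected_divergence(mirror, recs$t_i, recs$t_j, 0.02),
               tolerance = 1e-12)
  fit <- fit_model(recs, "ABneutral", restarts = 10L, seed = 2L, n_boot = 0L)
  # the unconstrained valley is flat: the curve is matched essentially
  # perfectly while the (alpha, beta) labels drift around the mirror pair
  expect_lt(fit$rss, 1e-9)
  rates <- sort(fit$estimate[c("alpha", "beta")])
  expect_lt(abs(rates[1L] - 2e-4) / 2e-4, 0.10)
  expect_lt(abs(rates[2L] - 6e-4) / 6e-4, 0.10)
})

test_that("model comparison selects by nested F-tests", {
  ped <- build_pedigree("MA1_2")
  truth <- inheritance_model(3e-4, 9e-4)
  recs <- exact_divergence_records(ped, truth, c_ = 0.01)
  set.seed(8)
  recs$D <- pmax(0, recs$D + rnorm(nrow(recs), 0, 1e-4))
  p_u <- truth$pi[1L]
  fits <- lapply(stats::setNames(c("ABneutral", "ABmm", "ABuu", "ABnull"),
                                 c("ABneutral", "ABmm", "ABuu", "ABnull")),
                 function(k) fit_model(recs, k, restarts = 6L, seed = 3L,
                                       n_boot = 0L, p_u = p_u))
  cmp <- compare_models(fits)
  expect_equal(cmp$selected, "ABneutral")
  expect_lt(cmp$tests$p[1L], 0.05)

  flat <- data.table::copy(recs)[, D := 0.07]
  flat_fits <- lapply(fits, function(f) {
    fit_model(flat, f$kind, restarts = 4L, seed = 4L, n_boot = 0L,
              p_u = if (f$kind == "ABnull") NULL else p_u)
  })
  expect_equal(compare_models(flat_fits)$selected, "ABnull")
  expect_error(compare_models(fits[1:3]), "all four")
})

test_that("residual bootstrap reports uncertainty for iid records", {
  ped <- build_pedigree("MA1_2")
  truth <- inheritance_model(3e-4, 9e-4)
  recs <- exact_divergence_records(ped, truth, c_ = 0.01)
  set.seed(12)
  recs$D <- pmax(0, recs$D + rnorm(nrow(recs), 0, 2e-4))
  fit <- fit_model(recs, "ABneutral", restarts = 5L, seed = 5L, n_boot = 30L,
                   p_u = truth$pi[1L])
  expect_true(all(fit$se[c("alpha", "c")] > 0))
  expect_lt(fit$ci[1L, "alpha"], fit$estimate[["alpha"]] + fit$se[["alpha"]])
})

test_that("region bootstrap intervals track the replicate-level noise", {
  ped <- build_pedigree("MA1_2")
  model <- inheritance_model(5e-4, 1.5e-3)
  states <- evolve_methylomes(5000L, ped, model, seed = 31)
  calls <- calls_from_states(states, sequenced_samples(ped))
  tab <- divergence_table(ped, calls)
  fit <- fit_model(tab, "ABneutral", restarts = 6L, seed = 6L, n_boot = 0L,
                   p_u = observed_proportions(calls)[["U"]])
  bfit <- bootstrap_rates(ped, calls, fit, n_boot = 40L, seed = 7L)
  expect_true(all(bfit$se[c("alpha", "beta")] > 0))
  expect_lt(bfit$ci[1L, "alpha"], fit$estimate[["alpha"]])
  expect_gt(bfit$ci[2L, "alpha"], fit$estimate[["alpha"]])
})
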