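#!/usr/bin/env Rscript

# Stage 5: fit the four selfing inheritance models (ABneutral, ABmm, ABuu,
# ABnull) to the divergence table, anchor gains vs losses with the observed
# unmethylated-region proportion, compare the models by nested F-tests, and
# wrap the neutral fit in region-bootstrap intervals. Recovered rates are
# compared with the planted truth from stage 1.

suppressMessages(library(epirate))

ped <- read_pedigree_tsv("results/sim/pedigree.tsv")
tab <- data.table::fread("results/divergence/divergence_CG.tsv")
calls_long <- data.table::fread("results/status/calls_CG.tsv")
truth <- jsonlite::read_json("results/sim/truth.json")
out <- "results/rates"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

status <- data.table::dcast(calls_long, region_id ~ sample,
                            value.var = "status")
ids <- status$region_id
status <- as.matrix(status[, -1L])
rownames(status) <- ids
retained <- calls_long$retained[match(ids, calls_long$region_id)]
p_u <- observed_proportions(status, retained = retained)[["U"]]

kinds <- c("ABneutral", "ABmm", "ABuu", "ABnull")
fits <- lapply(stats::setNames(kinds, kinds), function(k)
  fit_model(tab, kind = k, restarts = 10L, seed = 5L, n_boot = 0L, p_u = p_u))
calls <- structure(list(status = status, retained = retained,
                        region_id = ids,
                        samples = sequenced_samples(ped)),
                   class = "status_calls")
fits$ABneutral <- bootstrap_rates(ped, calls, fits$ABneutral,
                                  n_boot = 200L, seed = 6L)
cmp <- compare_models(fits)
write_fit_json(fits, cmp, file.path(out, "fits_CG.json"))

est <- fits$ABneutral$estimate
cat(sprintf("alpha = %.3g (planted %.3g, rel. error %.1f%%), 95%% CI [%.3g, %.3g]\n",
            est[["alpha"]], truth$alpha,
            100 * abs(est[["alpha"]] - truth$alpha) / truth$alpha,
            fits$ABneutral$ci[1L, "alpha"], fits$ABneutral$ci[2L, "alpha"]))
cat(sprintf("beta  = %.3g (planted %.3g, rel. error %.1f%%), 95%% CI [%.3g, %.3g]\n",
            est[["beta"]], truth$beta,
            100 * abs(est[["beta"]] - truth$beta) / truth$beta,
            fits$ABneutral$ci[1L, "beta"], fits$ABneutral$ci[2L, "beta"]))
cat(sprintf("beta/alpha = %.2f; selected model: %s\n",
            est[["beta"]] / est[["alpha"]], cmp$selected))
print(cmp$tests)
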