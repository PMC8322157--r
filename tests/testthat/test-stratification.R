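toy_regions <- function(spans, chrom = "chr1", context = "CG", n_c = NULL) {
  start <- vapply(spans, `[[`, numeric(1L), 1L)
  end <- vapply(spans, `[[`, numeric(1L), 2L)
  if (is.null(n_c)) n_c <- pmax(2L, as.integer((end - start) / 10))
  data.table::data.table(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    context = context, n_c = n_c, density = n_c / (end - start),
    region_id = sprintf("%s_%s_%d", context, chrom, start))
}

test_that("feature labels require 40% region-relative overlap", {
  regions <- toy_regions(list(c(100, 200), c(300, 400), c(600, 700)))
  features <- data.table::data.table(
    chrom = "chr1", start = c(150L, 361L, 580L, 640L),
    end = c(300L, 450L, 650L, 700L), strand = "+",
    type = c("gene", "gene", "gene", "TE"),
    id = c("g1", "g2", "g3", "t1"))
  lab <- assign_features(regions, features)
  ids <- function(l) sort(lab$region_id[lab$label == l])
  # overlap 50/100 for region 1; 39/100 for region 2 -> intergenic
  expect_equal(ids("gene"), sort(regions$region_id[c(1L, 3L)]))
  expect_equal(ids("intergenic"), regions$region_id[2L])
  # region 3 overlaps a gene (50%) and a TE (60%): both labels
  expect_true(all(c("gene", "TE") %in% lab$label[lab$region_id == regions$region_id[3L]]))
  expect_error(assign_features(regions, data.table::copy(features)[, chrom := "chrX"]),
               "absent")
})

test_that("promoters extend 1.5 kb upstream of the TSS with bound clamping", {
  genes <- data.table::data.table(
    chrom = "chr1", start = c(5000L, 5000L, 400L),
    end = c(7000L, 7000L, 900L), strand = c("+", "-", "+"),
    id = c("g1", "g2", "g3"))
  pr <- make_promoters(genes, chrom_lengths = c(chr1 = 8000L))
  expect_equal(pr$start, c(3500L, 7000L, 0L))
  expect_equal(pr$end, c(5000L, 8000L, 400L))
  expect_true(all(pr$type == "promoter"))
})

test_that("gbM splitting follows the gene id list", {
  labels <- data.table::data.table(
    region_id = c("r1", "r2", "r3", "r3"),
    label = c("gene", "gene", "gene", "gene"),
    feature_id = c("g1", "g2", "g1", "g2"))
  out <- split_gbM(labels, gbm_ids = "g1")
  expect_true("gbM_gene" %in% out$label[out$region_id == "r1"])
  expect_true("non_gbM_gene" %in% out$label[out$region_id == "r2"])
  # region over one gbM and one non-gbM gene carries both labels
  r3 <- out$label[out$region_id == "r3"]
  expect_true(all(c("gbM_gene", "non_gbM_gene") %in% r3))
  out0 <- split_gbM(labels, gbm_ids = character(0))
  expect_false("gbM_gene" %in% out0$label)
  expect_warning(split_gbM(labels, gbm_ids = c("g1", "gX")), "absent")
})

test_that("shape classes split duplets and multiplets at the published medians", {
  regions <- rbind(
    toy_regions(list(c(1, 3)), n_c = 2L),
    toy_regions(list(c(100, 250)), n_c = 20L),
    toy_regions(list(c(400, 504)), n_c = 4L))
  cls <- classify_shape(regions)
  expect_equal(cls$size_class, c("duplet", "multiplet_long", "multiplet_short"))
  expect_equal(cls$density_class, c(NA, "dense", "sparse"))
  expect_error(classify_shape(data.table::copy(regions)[, context := "CHH"]),
               "CG")
})

test_that("zone assignment uses the region midpoint against a tiling partition", {
  partition <- data.table::data.table(
    chrom = "chr1", start = c(0L, 400L, 700L),
    end = c(400L, 700L, 1000L),
    zone = c("arm", "pericentromere", "centromere"))
  regions <- toy_regions(list(c(100, 200), c(380, 440), c(800, 900)))
  z <- assign_zone(regions, partition)
  expect_equal(z, c("arm", "pericentromere", "centromere"))
  expect_error(assign_zone(data.table::copy(regions)[, chrom := "chr2"], partition),
               "missing chromosome")
  gap <- partition[-2L]
  expect_error(assign_zone(regions, gap), "gap")
})

test_that("stratified fits reduce to the genome-wide fit on the full stratum", {
  ped <- build_pedigree("MA1_2")
  model <- inheritance_model(5e-4, 1.5e-3)
  states <- evolve_methylomes(3000L, ped, model, seed = 41)
  calls <- calls_from_states(states, sequenced_samples(ped))
  tab <- divergence_table(ped, calls)
  full <- fit_model(tab, "ABneutral", restarts = 5L, seed = 2L, n_boot = 0L,
                    p_u = observed_proportions(calls)[["U"]])
  sr <- stratified_rates(list(all = calls$region_id), ped, calls,
                         restarts = 5L, seed = 2L)
  expect_equal(sr$all$fits$ABneutral$estimate, full$estimate, tolerance = 1e-8)
  expect_warning(
    sr2 <- stratified_rates(list(none = character(0)), ped, calls),
    "empty")
  expect_null(sr2$none)
  expect_warning(
    sr3 <- stratified_rates(list(tiny = calls$region_id[1:5]), ped, calls),
    "unstable")
  expect_false(sr3$tiny$stable)
})

test_that("planted per-stratum rate multipliers reappear in the fits", {
  ped <- build_pedigree("MA1_2")
  samples <- sequenced_samples(ped)
  n <- 4000L
  st <- rbind(
    evolve_methylomes(n / 2, ped, inheritance_model(6e-4, 2.3e-3), seed = 43),
    evolve_methylomes(n / 2, ped, inheritance_model(1.2e-4, 4.6e-4), seed = 44))
  calls <- calls_from_states(st, samples)
  strata <- list(gene = calls$region_id[1:(n / 2)],
                 intergenic = calls$region_id[(n / 2 + 1):n])
  sr <- stratified_rates(strata, ped, calls, restarts = 5L, seed = 3L)
  expect_gt(sr$gene$fits$ABneutral$estimate[["alpha"]],
            sr$intergenic$fits$ABneutral$estimate[["alpha"]])
  expect_gt(sr$gene$fits$ABneutral$estimate[["beta"]],
            sr$intergenic$fits$ABneutral$estimate[["beta"]])
})

test_that("label proportions for regions track those for single cytosines", {
  # uniformly placed features over a synthetic genome: region-level and
  # site-level annotation fractions should agree closely
  sim <- simulate_genome(60000L, seed = 13, cg_enrich = 0)
  seg <- segment_genome(sim$genome, "CG")
  lab <- assign_features(seg$regions, sim$annotation)
  gene_regions <- unique(lab$region_id[lab$label == "gene"])
  frac_regions <- length(gene_regions) / nrow(seg$regions)
  site_regions <- assign_sites(seg$sites, seg$regions)
  frac_sites <- mean(site_regions %in% gene_regions)
  expect_lt(abs(frac_regions - frac_sites), 0.05)
})
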