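test_that("cytosine scanning classifies both strands by trinucleotide context", {
  cg <- scan_cytosines(c(chrA = "ACGTA"), "CG")
  expect_equal(cg$pos, c(1L, 2L))
  expect_equal(cg$strand, c("+", "-"))

  for (ctx in c("CG", "CHG", "CHH"))
    expect_equal(nrow(scan_cytosines(c(chrA = "AAAAA"), ctx)), 0L)

  # CCGG: the outer Cs read CHG on their strands, the inner dyad is CG
  expect_equal(scan_cytosines(c(chrA = "CCGG"), "CG")[, .(pos, strand)],
               data.table::data.table(pos = c(1L, 2L), strand = c("+", "-")))
  expect_equal(scan_cytosines(c(chrA = "CCGG"), "CHG")[, .(pos, strand)],
               data.table::data.table(pos = c(0L, 3L), strand = c("+", "-")))
  expect_equal(nrow(scan_cytosines(c(chrA = "CCGG"), "CHH")), 0L)

  # N never matches
  expect_equal(nrow(scan_cytosines(c(chrA = "ACNGT"), "CHG")), 0L)

  expect_error(scan_cytosines(character(0), "CG"), "empty")
  expect_error(scan_cytosines(c(chrA = "ACGT"), "CpG"), "context")
})

test_that("seed construction pairs symmetric sites and covers every cytosine", {
  cg <- scan_cytosines(c(chrA = "ACGTA"), "CG")
  seeds <- build_seeds(cg, "CG")
  expect_equal(seeds[, .(start, end, n_c)],
               data.table::data.table(start = 1L, end = 3L, n_c = 2L))

  # CAG: symmetric CHG triad spanning [0, 3)
  chg <- scan_cytosines(c(chrA = "ACAGA"), "CHG")
  expect_equal(build_seeds(chg, "CHG")[, .(start, end, n_c)],
               data.table::data.table(start = 1L, end = 4L, n_c = 2L))

  # every individual CHH is its own seed
  chh <- data.table::data.table(chrom = "c", pos = c(5L, 9L),
                                strand = c("+", "-"), context = "CHH")
  expect_equal(build_seeds(chh, "CHH")[, .(start, end)],
               data.table::data.table(start = c(5L, 9L), end = c(6L, 10L)))

  # unpaired CHG (CCG has no symmetric partner) becomes a singleton seed
  ccg <- scan_cytosines(c(chrA = "ACCGA"), "CHG")
  expect_equal(nrow(ccg), 1L)
  expect_equal(build_seeds(ccg, "CHG")$n_c, 1L)

  # a CG without its dyad partner indicates inconsistent scanning
  broken <- data.table::data.table(chrom = "c", pos = 1L, strand = "+",
                                   context = "CG")
  expect_error(build_seeds(broken, "CG"), "symmetric")
})

test_that("merging follows the iterative distance rule with the span cap", {
  dyads <- function(starts) data.table::data.table(
    chrom = "c1", start = starts, end = starts + 2L, context = "CG", n_c = 2L)

  r <- merge_regions(dyads(c(1L, 7L)))
  expect_equal(r[, .(start, end, n_c)],
               data.table::data.table(start = 1L, end = 9L, n_c = 4L))

  r <- merge_regions(dyads(c(0L, 202L)))
  expect_equal(nrow(r), 2L)

  # left-to-right greedy at gap 88: third merge would exceed the cap
  r <- merge_regions(dyads(c(0L, 90L, 180L, 270L)))
  expect_equal(r[, .(start, end)],
               data.table::data.table(start = c(0L, 270L), end = c(182L, 272L)))

  # adjacent clusters at gap 0 merge first
  r <- merge_regions(dyads(c(0L, 2L)))
  expect_equal(r[, .(start, end, n_c)],
               data.table::data.table(start = 0L, end = 4L, n_c = 4L))

  expect_error(merge_regions(data.table::data.table(
    chrom = "c1", start = c(0L, 1L), end = c(3L, 4L), context = "CG",
    n_c = 2L)), "overlap")
})

test_that("merged regions cover every scanned cytosine exactly once within the cap", {
  for (seed in 1:5) {
    g <- random_genome(1500L, seed = seed)
    for (ctx in c("CG", "CHG", "CHH")) {
      sites <- scan_cytosines(g, ctx)
      if (nrow(sites) == 0L) next
      regions <- merge_regions(build_seeds(sites, ctx))
      expect_true(all(regions$end - regions$start <= 185L))
      ids <- assign_sites(sites, regions)
      expect_false(anyNA(ids))
      expect_equal(sum(regions$n_c), nrow(sites))
      # per-region assignment counts agree with the recorded n_c
      cnt <- table(ids)
      expect_equal(as.integer(cnt[regions$region_id]), regions$n_c)
      # no two regions of a context overlap
      o <- order(regions$chrom, regions$start)
      same <- regions$chrom[o][-1L] == regions$chrom[o][-nrow(regions)]
      expect_true(all(regions$start[o][-1L][same] >=
                        regions$end[o][-nrow(regions)][same]))
    }
  }
})

test_that("re-merging merged regions is a fixpoint up to the span cap", {
  g <- random_genome(2000L, seed = 42)
  sites <- scan_cytosines(g, "CG")
  regions <- merge_regions(build_seeds(sites, "CG"))
  again <- merge_regions(regions[, .(chrom, start, end, context, n_c)])
  expect_equal(nrow(again), nrow(regions))
  # every adjacent output pair is separated by > 185 bp or blocked by the cap
  gaps <- regions$start[-1L] - regions$end[-nrow(regions)]
  spans <- regions$end[-1L] - regions$start[-nrow(regions)]
  expect_true(all(gaps > 185L | spans > 185L))
})

test_that("fixed-width bins tile chromosomes and count member cytosines", {
  bins <- bin_genome(c(chr1 = 250L), width = 100L)
  expect_equal(bins[, .(start, end)],
               data.table::data.table(start = c(0L, 100L, 200L),
                                      end = c(100L, 200L, 250L)))
  sites <- data.table::data.table(
    chrom = "chr1", pos = c(1L, 2L, 150L, 151L),
    strand = c("+", "-", "+", "-"), context = "CG")
  bins <- bin_genome(c(chr1 = 250L), width = 100L, sites = sites)
  expect_equal(bins$n_c, c(2L, 2L, 0L))
  expect_error(bin_genome(c(chr1 = 250L), width = 0L), "width")
})

test_that("autocorrelation reproduces direct Pearson values and flags degeneracy", {
  sites <- data.table::data.table(chrom = "c", pos = c(0L, 3L, 6L, 9L),
                                  level = c(1, 0, 1, 0))
  prof <- autocorrelation(sites, d_max = 6L)
  expect_equal(prof$r[3L], -1)
  expect_equal(prof$n_pairs[3L], 3L)
  expect_equal(prof$r[6L], 1)
  expect_equal(prof$n_pairs[6L], 2L)
  expect_true(is.na(prof$r[1L]) && prof$n_pairs[1L] == 0L)

  flat <- data.table::data.table(chrom = "c", pos = c(0L, 1L, 2L, 3L),
                                 level = 0.8)
  expect_true(all(is.na(autocorrelation(flat, 2L)$r)))
  expect_error(autocorrelation(sites, 0L), "d_max")
})

test_that("region summaries report medians and the small-region fraction", {
  regions <- data.table::data.table(
    chrom = "c", start = c(0L, 10L, 30L), end = c(10L, 20L, 40L),
    context = "CG", n_c = c(2L, 8L, 10L),
    density = c(0.2, 0.8, 1.0), region_id = c("a", "b", "c"))
  s <- region_summary(regions)
  expect_equal(s$median_n_c, 8)
  expect_equal(s$frac_le2_c, 1 / 3)
  regions2 <- rbind(regions, regions[1])
  expect_equal(region_summary(regions2)$frac_le2_c, 0.5)
  expect_equal(region_summary(regions[2])$median_density, 0.8)
  expect_error(region_summary(regions[0]), "empty")
})
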