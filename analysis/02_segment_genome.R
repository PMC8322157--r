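#!/usr/bin/env Rscript

# Stage 2: partition the genome into CG/CHG/CHH cytosine-cluster regions by
# seed-and-merge (185 bp cap), compare against 100 bp bins, and compute the
# methylation autocorrelation profile that motivates the cutoff.

suppressMessages(library(epirate))

genome <- read_genome_fasta("results/sim/genome.fa")
counts <- read_counts_tsv("results/sim/counts.tsv")
out <- "results/segmentation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

summary_rows <- list()
for (ctx in c("CG", "CHG", "CHH")) {
  seg <- segment_genome(genome, ctx)
  write_regions_bed(seg$regions, file.path(out, paste0("regions_", ctx, ".bed")))
  s <- region_summary(seg$regions)
  bins <- bin_genome(vapply(genome, nchar, integer(1L)), width = 100L,
                     sites = seg$sites)
  sb <- region_summary(bins[bins$n_c > 0L])
  summary_rows[[ctx]] <- data.table::data.table(
    context = ctx, unit = c("region", "bin100"),
    n = c(s$n_regions, sb$n_regions),
    median_n_c = c(s$median_n_c, sb$median_n_c),
    max_n_c = c(s$max_n_c, sb$max_n_c),
    median_density = c(s$median_density, sb$median_density),
    frac_le2_c = c(s$frac_le2_c, sb$frac_le2_c))
  cat(sprintf("%s: %d regions, median %g Cs (max %d), median density %.3f\n",
              ctx, s$n_regions, s$median_n_c, s$max_n_c, s$median_density))
}
data.table::fwrite(data.table::rbindlist(summary_rows),
                   file.path(out, "summary.tsv"), sep = "\t")

# autocorrelation of per-cytosine methylation levels for one sample
sample1 <- sub("^meth_", "", grep("^meth_", names(counts), value = TRUE)[1L])
for (ctx in intersect(c("CG", "CHG"), unique(counts$context))) {
  sites <- scan_cytosines(genome, ctx)
  idx <- sites[counts[counts$context == ctx], on = c("chrom", "pos"),
               nomatch = NULL]
  idx$level <- idx[[paste0("meth_", sample1)]] / pmax(idx[[paste0("total_", sample1)]], 1L)
  prof <- autocorrelation(idx[, .(chrom, pos, level)], d_max = 300L)
  data.table::fwrite(prof, file.path(out, paste0("autocorrelation_", ctx, ".tsv")),
                     sep = "\t")
  near <- mean(prof$r[prof$distance <= 50 & !is.na(prof$r)])
  far <- mean(prof$r[prof$distance > 250 & !is.na(prof$r)])
  cat(sprintf("%s autocorrelation: mean r %.3f at <=50 bp vs %.3f at >250 bp\n",
              ctx, near, far))
}
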