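#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs — a genome with planted
# gene/TE annotation and chromosome zones, a mutation-accumulation pedigree,
# region methylomes evolved under known gain/loss rates, and per-cytosine
# bisulfite counts. Everything downstream reads these files.

suppressMessages(library(epirate))

seed <- 11L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

alpha <- 1.2e-4   # planted CG gain rate (per allele per generation)
beta <- 4.6e-4    # planted CG loss rate

sim <- simulate_genome(length = 120000L, n_chrom = 2L, seed = seed)
write_genome_fasta(sim$genome, file.path(out, "genome.fa"))
write_annotation_gff(sim$annotation, file.path(out, "annotation.gff3"))
data.table::fwrite(sim$zones, file.path(out, "zones.bed"), sep = "\t",
                   col.names = FALSE)

ped <- build_pedigree("MA1_2")
write_pedigree_tsv(ped, file.path(out, "pedigree.tsv"))

seg <- segment_genome(sim$genome, "CG")
model <- inheritance_model(alpha, beta)
states <- evolve_methylomes(nrow(seg$regions), ped, model, seed = seed + 1L)
sites <- data.table::copy(seg$sites)
sites[, region_idx := match(assign_sites(sites, seg$regions),
                            seg$regions$region_id)]
counts <- emit_counts(states, sites, samples = sequenced_samples(ped),
                      coverage = list(mean = 8, size = 5), seed = seed + 2L)
write_counts_tsv(counts, file.path(out, "counts.tsv"))
jsonlite::write_json(
  list(seed = seed, alpha = alpha, beta = beta, preset = "MA1_2",
       n_regions = nrow(seg$regions),
       genome_length = unname(sim$chrom_lengths)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("simulated", length(sim$genome), "chromosomes,",
    nrow(seg$regions), "CG regions,",
    length(sequenced_samples(ped)), "sequenced samples\n")
cat("planted rates: alpha =", alpha, ", beta =", beta, "\n")
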