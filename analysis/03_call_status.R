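#!/usr/bin/env Rscript

# Stage 3: aggregate per-cytosine counts into CG regions, apply the
# coverage filter (> 3 reads per cytosine in every sample), fit the
# three-component binomial mixture, and call U/I/M status with the 0.99
# posterior retention rule.

suppressMessages(library(epirate))

genome <- read_genome_fasta("results/sim/genome.fa")
counts <- read_counts_tsv("results/sim/counts.tsv")
ped <- read_pedigree_tsv("results/sim/pedigree.tsv")
out <- "results/status"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seg <- segment_genome(genome, "CG")
samples <- sequenced_samples(ped)
rc <- aggregate_counts(counts[counts$context == "CG"], seg$regions)
covmask <- coverage_filter(rc, seg$regions, samples = samples)
sub <- structure(list(meth = rc$meth[covmask, samples, drop = FALSE],
                      total = rc$total[covmask, samples, drop = FALSE],
                      region_id = rc$region_id[covmask], samples = samples),
                 class = "region_counts")
model <- fit_status_model(sub$meth, sub$total)
calls <- call_status(sub, model)

cat(sprintf("coverage filter: %.1f%% of %d regions pass\n",
            100 * mean(covmask), length(covmask)))
cat(sprintf("mixture components: p = (%.3f, %.3f, %.3f), weights = (%.2f, %.2f, %.2f)\n",
            model$p[1], model$p[2], model$p[3],
            model$weight[1], model$weight[2], model$weight[3]))
cat(sprintf("posterior filter: %.1f%% of covered regions retained\n",
            100 * mean(calls$retained)))
prop <- observed_proportions(calls)
cat(sprintf("state proportions among retained calls: U %.2f, I %.2f, M %.2f\n",
            prop["U"], prop["I"], prop["M"]))

calls_long <- data.table::data.table(
  region_id = rep(calls$region_id, length(samples)),
  sample = rep(samples, each = length(calls$region_id)),
  status = as.vector(calls$status),
  posterior = as.vector(calls$posterior),
  retained = rep(calls$retained, length(samples)))
data.table::fwrite(calls_long, file.path(out, "calls_CG.tsv"), sep = "\t")
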