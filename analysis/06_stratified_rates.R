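#!/usr/bin/env Rscript

# Stage 6: annotation-stratified rate estimation — label CG regions by
# gene/TE/UTR/promoter overlap (>= 40% of the region span), chromosome zone
# (midpoint rule) and shape class, then refit the neutral model per stratum.

suppressMessages(library(epirate))

genome <- read_genome_fasta("results/sim/genome.fa")
ann <- read_annotation_gff("results/sim/annotation.gff3")
zones <- read_zones_bed("results/sim/zones.bed")
ped <- read_pedigree_tsv("results/sim/pedigree.tsv")
calls_long <- data.table::fread("results/status/calls_CG.tsv")
out <- "results/stratified"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seg <- segment_genome(genome, "CG")
genes <- ann[ann$type == "gene"]
features <- rbind(ann, make_promoters(genes, chrom_lengths =
                                        vapply(genome, nchar, integer(1L))),
                  fill = TRUE)
labels <- assign_features(seg$regions, features)
# synthetic gbM list: half of the planted genes, lexicographically first
gbm <- sort(genes$id)[seq_len(nrow(genes) %/% 2L)]
labels <- split_gbM(labels, gbm)
shape <- classify_shape(seg$regions)
zone <- assign_zone(seg$regions, zones)
label_table <- merge(labels, shape, by = "region_id", all.x = TRUE)
label_table$zone <- zone[match(label_table$region_id, seg$regions$region_id)]
data.table::fwrite(label_table, file.path(out, "labels_CG.tsv"), sep = "\t")

status <- data.table::dcast(calls_long, region_id ~ sample,
                            value.var = "status")
ids <- status$region_id
status <- as.matrix(status[, -1L])
rownames(status) <- ids
calls <- structure(list(
  status = status,
  retained = calls_long$retained[match(ids, calls_long$region_id)],
  region_id = ids, samples = sequenced_samples(ped)),
  class = "status_calls")

by_label <- split(labels$region_id, labels$label)
by_zone <- split(seg$regions$region_id, zone)
by_shape <- split(shape$region_id, shape$size_class)
sr <- stratified_rates(c(by_label, by_zone, by_shape), ped, calls,
                       kinds = "ABneutral", min_regions = 100L,
                       restarts = 8L, seed = 7L)

rows <- data.table::rbindlist(lapply(names(sr), function(nm) {
  f <- sr[[nm]]$fits$ABneutral
  data.table::data.table(
    stratum = nm, n_regions = sr[[nm]]$n_regions,
    alpha = if (is.null(f)) NA_real_ else f$estimate[["alpha"]],
    beta = if (is.null(f)) NA_real_ else f$estimate[["beta"]],
    beta_alpha = if (is.null(f)) NA_real_ else
      f$estimate[["beta"]] / f$estimate[["alpha"]],
    stable = sr[[nm]]$stable)
}))
data.table::fwrite(rows, file.path(out, "stratified_rates_CG.tsv"), sep = "\t")
print(rows)
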