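# Readers and writers for the pipeline's file dialects. Internal
# coordinates are 0-based half-open; TSV positions are 1-based, BED/GFF
# follow their own conventions via rtracklayer.

#' Read a genome FASTA
#' @param path FASTA file (gzip allowed).
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write a genome FASTA
#' @param genome Named character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome)), path)
  invisible(path)
}

#' Read a per-cytosine count TSV
#'
#' Expected columns: `chrom`, `pos` (1-based position of the C), `strand`,
#' `context`, then `meth_<sample>` / `total_<sample>` pairs. Positions are
#' converted to the package's 0-based convention.
#'
#' @param path TSV file.
#' @return data.table in the internal dialect.
#' @export
read_counts_tsv <- function(path) {
  x <- data.table::fread(path)
  req <- c("chrom", "pos", "strand", "context")
  if (!all(req %in% names(x))) stop("count TSV must carry columns: ",
                                    paste(req, collapse = ", "))
  .count_samples(x)  # validates meth_/total_ pairing
  x[, pos := as.integer(pos) - 1L]
  x[]
}

#' Write a per-cytosine count TSV (1-based positions)
#' @param counts Internal count table (0-based).
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- data.table::copy(counts)
  out[, pos := pos + 1L]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write regions as BED6 (name = region id, score = cytosine count)
#' @param regions Region table.
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.table::data.table(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions$region_id, score = regions$n_c, strand = ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read regions back from BED6
#' @param path BED file written by [write_regions_bed()].
#' @param context Context label to attach.
#' @return Region table.
#' @export
read_regions_bed <- function(path, context = NA_character_) {
  x <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  data.table::data.table(
    chrom = x$chrom, start = x$start, end = x$end, context = context,
    n_c = as.integer(x$score), density = x$score / (x$end - x$start),
    region_id = x$name)
}

#' Read a chromosome-partition BED (zone in the name column)
#' @param path BED file with at least chrom/start/end/zone columns.
#' @return data.table chrom/start/end/zone.
#' @export
read_zones_bed <- function(path) {
  x <- data.table::fread(path, header = FALSE)
  data.table::setnames(x, seq_len(4L), c("chrom", "start", "end", "zone"))
  x[, .(chrom, start = as.integer(start), end = as.integer(end), zone)]
}

#' Read annotation features from GFF3
#'
#' @param path GFF3 file.
#' @param types Feature types to keep, mapped to the label vocabulary
#'   (`gene`, `TE`, `UTR5`, `UTR3`).
#' @return data.table chrom/start/end/strand/type/id (0-based half-open).
#' @export
read_annotation_gff <- function(path,
                                types = c(gene = "gene",
                                          transposable_element = "TE",
                                          five_prime_UTR = "UTR5",
                                          three_prime_UTR = "UTR3")) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% names(types)
  gr <- gr[keep]
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = unname(types[as.character(gr$type)]),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_)
}

#' Write annotation features as GFF3
#' @param features data.table chrom/start/end/strand/type/id (0-based).
#' @param path Output file.
#' @export
write_annotation_gff <- function(features, path) {
  type_map <- c(gene = "gene", TE = "transposable_element",
                UTR5 = "five_prime_UTR", UTR3 = "three_prime_UTR",
                promoter = "promoter")
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"),
    type = unname(type_map[features$type]),
    ID = features$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a pedigree TSV (columns id, parent, generation, sequenced)
#' @param path TSV file; `parent` empty or NA for the founder.
#' @return A [pedigree()].
#' @export
read_pedigree_tsv <- function(path) {
  x <- data.table::fread(path, na.strings = c("", "NA"))
  x[, sequenced := as.logical(sequenced)]
  pedigree(x)
}

#' Write a pedigree TSV
#' @param ped A [pedigree()].
#' @param path Output file.
#' @export
write_pedigree_tsv <- function(ped, path) {
  data.table::fwrite(data.table::as.data.table(ped), path, sep = "\t")
  invisible(path)
}

#' Write a fit report as JSON
#'
#' @param fits Named list of `rate_fit` objects.
#' @param comparison Optional `model_comparison`.
#' @param path Output file.
#' @export
write_fit_json <- function(fits, comparison = NULL, path) {
  report <- list(
    models = lapply(fits, function(f) list(
      kind = f$kind, estimate = as.list(f$estimate), rss = f$rss,
      n_obs = f$n_obs, n_params = f$n_params,
      se = if (!is.null(f$se)) as.list(f$se) else NULL,
      converged = f$converged)),
    selected = if (!is.null(comparison)) comparison$selected else NULL,
    tests = if (!is.null(comparison)) comparison$tests else NULL)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
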