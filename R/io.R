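# Readers and writers for the on-disk interchange formats: FASTA (genome,
# probes), GTF (transcript models), TSV (probes, expression, calls, sample
# metadata, Ct tables) and JSON (ground truth, reports). Models use GTF's
# 1-based closed coordinates on disk and this package's 0-based half-open
# coordinates in memory.

#' @rdname sim_io
#' @param genome named character vector of chromosome sequences.
#' @param path output/input file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(drop_attributes(genome)), path)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname sim_io
#' @param models transcript-model data.frame.
#' @export
write_models_gtf <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand, type = "exon", source = "intronsig",
    gene_id = models$gene_id, transcript_id = models$transcript_id,
    refseq = as.character(models$refseq))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname sim_io
#' @export
read_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  refseq <- if (!is.null(gr$refseq)) as.logical(gr$refseq) else TRUE
  transcript_models(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    refseq = refseq)
}

#' @rdname sim_io
#' @param probes long data.frame probeset_id, probe_index, sequence.
#' @export
write_probes_fasta <- function(probes, path) {
  seqs <- Biostrings::DNAStringSet(probes$sequence)
  names(seqs) <- sprintf("%s_%d", probes$probeset_id, probes$probe_index)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Simulation/interchange readers and writers
#'
#' Plain-text persistence for every object the pipeline exchanges.
#'
#' @name sim_io
#' @param x a data.frame to write.
#' @return readers return the parsed object; writers return the path,
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sim_io
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname sim_io
#' @param se expression SummarizedExperiment.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_expression_set <- function(se, dir, prefix = "expression") {
  p <- function(what) file.path(dir, sprintf("%s_%s.tsv", prefix, what))
  x <- data.frame(probeset_id = rownames(se), exprs_of(se),
                  check.names = FALSE)
  cl <- data.frame(probeset_id = rownames(se), calls_of(se),
                   check.names = FALSE)
  write_tsv(x, p("exprs"))
  write_tsv(cl, p("calls"))
  write_tsv(samples_of(se), p("samples"))
  invisible(dir)
}

#' @rdname sim_io
#' @param exprs_path,calls_path,samples_path the three TSV files written by
#'   \code{write_expression_set}.
#' @export
read_expression_set <- function(exprs_path, calls_path, samples_path) {
  x <- read_tsv(exprs_path)
  cl <- read_tsv(calls_path)
  samples <- read_tsv(samples_path)
  ids <- x$probeset_id
  xm <- as.matrix(x[, -1, drop = FALSE])
  cm <- as.matrix(cl[match(ids, cl$probeset_id), -1, drop = FALSE])
  rownames(xm) <- rownames(cm) <- ids
  expression_matrix(xm, cm, samples)
}

#' @rdname sim_io
#' @param truth a \code{sim_truth} object.
#' @export
write_truth_json <- function(truth, path) {
  ser <- lapply(unclass(truth), function(el) {
    if (is.matrix(el)) {
      as.data.frame(el)
    } else el
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write a full simulated dataset to a directory
#'
#' Genome FASTA, transcript-model GTF, probe FASTA and TSV, expression +
#' calls + sample TSVs, Ct-table TSV and ground-truth JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_models_gtf(sim$models, file.path(dir, "models.gtf"))
  write_probes_fasta(sim$probes, file.path(dir, "probes.fasta"))
  write_tsv(sim$probes, file.path(dir, "probes.tsv"))
  write_tsv(sim$probesets, file.path(dir, "probesets.tsv"))
  write_expression_set(sim$expression, dir)
  if (!is.null(sim$qrt)) write_tsv(sim$qrt, file.path(dir, "ct_table.tsv"))
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
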