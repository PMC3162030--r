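# Transcript models: a data.frame with one row per exon and columns
#   gene_id, transcript_id, chrom, strand, start, end, refseq
# Coordinates are 0-based, half-open; exons of a transcript are sorted and
# non-overlapping; introns are the gaps between consecutive exons; the gene
# span runs from the first exon start to the last exon end.

#' Assemble a transcript-model table
#'
#' @param gene_id,transcript_id,chrom,strand,start,end,refseq per-exon
#'   vectors; \code{start}/\code{end} are 0-based half-open.
#' @return validated transcript-model data.frame.
#' @export
transcript_models <- function(gene_id, transcript_id, chrom, strand, start,
                              end, refseq = TRUE) {
  m <- data.frame(gene_id = as.character(gene_id),
                  transcript_id = as.character(transcript_id),
                  chrom = as.character(chrom), strand = as.character(strand),
                  start = as.integer(start), end = as.integer(end),
                  refseq = as.logical(refseq), stringsAsFactors = FALSE)
  validate_models(m)
}

validate_models <- function(m) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end", "refseq")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("model table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(m$end <= m$start)) stopf("exon intervals must be non-empty (end > start)")
  if (!all(m$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  m <- m[order(m$gene_id, m$transcript_id, m$start), , drop = FALSE]
  overlaps <- unlist(lapply(split(seq_len(nrow(m)), m$transcript_id), function(i) {
    if (length(i) > 1L) any(m$start[i][-1] < m$end[i][-length(i)]) else FALSE
  }))
  if (any(overlaps)) stopf("overlapping exons within a transcript")
  rownames(m) <- NULL
  m
}

#' Gene spans (5'-most start to 3'-most end)
#'
#' @param models transcript-model data.frame.
#' @return one row per gene: gene_id, chrom, strand, start, end.
#' @export
gene_spans <- function(models) {
  sp <- do.call(rbind, lapply(split(models, models$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

# exon intervals of one gene (union over its transcripts), sorted and merged
gene_exon_intervals <- function(models, gene) {
  g <- models[models$gene_id == gene, , drop = FALSE]
  if (!nrow(g)) stopf("no model for gene '%s'", gene)
  iv <- g[order(g$start), c("start", "end")]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(merged)
    if (iv$start[i] <= merged$end[k]) {
      merged$end[k] <- max(merged$end[k], iv$end[i])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  merged
}

#' Intron intervals of a gene
#'
#' Gaps between the merged exon intervals of all the gene's transcripts,
#' 0-based half-open genomic coordinates.
#'
#' @param models transcript-model data.frame.
#' @param gene gene identifier.
#' @return data.frame with columns start, end (possibly zero rows).
#' @export
gene_introns <- function(models, gene) {
  ex <- gene_exon_intervals(models, gene)
  if (nrow(ex) < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

# 0-based half-open substring of a chromosome
genome_substr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
  substr(genome[[chrom]], start + 1L, end)
}

#' Spliced transcript sequences
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements for minus-strand transcripts, yielding the mature
#' mRNA (sense-strand) sequence.
#'
#' @param models transcript-model data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return named character vector, one element per transcript_id.
#' @export
spliced_sequences <- function(models, genome) {
  res <- vapply(split(models, models$transcript_id), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    s <- paste(mapply(genome_substr, start = tr$start, end = tr$end,
                      MoreArgs = list(genome = genome, chrom = tr$chrom[1])),
               collapse = "")
    if (tr$strand[1] == "-") revcomp(s) else s
  }, character(1))
  res
}

#' Gene-span genomic sequences
#'
#' Plus-strand genomic sequence of each gene span (all bases between the
#' 5'-most start and the 3'-most end of the gene's exons).
#'
#' @inheritParams spliced_sequences
#' @return named character vector, one element per gene_id.
#' @export
gene_span_sequences <- function(models, genome) {
  sp <- gene_spans(models)
  setNames(mapply(genome_substr, chrom = sp$chrom, start = sp$start, end = sp$end,
                  MoreArgs = list(genome = genome)),
           sp$gene_id)
}
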