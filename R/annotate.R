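# Probe-set re-annotation.
#
# Two-stage cascade: probe sets matching a reference mRNA (>= min_probes of
# their 25-mers perfectly) are mRNA; the remainder are aligned to genomic
# gene spans and called intronic only when every matching probe lies on the
# coding strand entirely within intron intervals. Probes occurring at more
# genomic loci than repeat_threshold mark the set as repeat; multi-gene,
# exon-overlapping or antisense-only matches are ambiguous; the rest are
# unmapped.

#' Count perfectly matching probes per target
#'
#' @param probes character vector: the probe set's sequences (typically 11
#'   25-mers).
#' @param index a [build_match_index()] object over the targets.
#' @return list with \code{counts} (named integer: distinct probes matched
#'   per target, a probe matching one target several times counting once)
#'   and \code{matches} (data.frame probe_index, target, offset, strand).
#' @export
match_probe_set <- function(probes, index) {
  hits <- query_index(index, probes)
  hits$probe_index <- match(hits$query, probes)
  counts <- vapply(split(hits$probe_index, hits$target),
                   function(i) length(unique(i)), 0L)
  list(counts = counts,
       matches = hits[, c("probe_index", "target", "offset", "strand")])
}

#' Call matched targets from per-target probe counts
#'
#' A probe set matches a target when at least \code{min_probes} of its
#' probes align perfectly to it.
#'
#' @param counts named integer vector from [match_probe_set()].
#' @param min_probes match threshold (default 8, of 11).
#' @return character vector of matched target names (possibly several;
#'   disambiguation is the classifier's job).
#' @export
call_probeset_target <- function(counts, min_probes = 8L) {
  names(counts)[counts >= min_probes]
}

#' Classify one probe set
#'
#' Applies the annotation cascade given match results against reference
#' mRNAs, gene spans and the whole genome:
#' \enumerate{
#'   \item at least \code{min_probes} probes matching any RefSeq transcript
#'     sequence: \code{mRNA};
#'   \item otherwise, any probe occurring at more than
#'     \code{repeat_threshold} genomic windows: \code{repeat};
#'   \item otherwise, \code{min_probes} matching exactly one gene span:
#'     \code{intronic} if every matching probe is on the coding strand and
#'     entirely within intron intervals, \code{ambiguous} if any matching
#'     probe overlaps an exon or a junction, or if all matches are
#'     antisense;
#'   \item \code{min_probes} matches on more than one gene span:
#'     \code{ambiguous};
#'   \item otherwise \code{unmapped}.
#' }
#'
#' @param probeset_id identifier.
#' @param probes the probe set's sequences.
#' @param mrna_index index over RefSeq transcript sequences (names =
#'   transcript_id).
#' @param span_index index over plus-strand gene-span sequences (names =
#'   gene_id).
#' @param genome_index index over chromosome sequences.
#' @param models transcript-model data.frame (supplies strand and intron
#'   intervals for matched gene spans).
#' @param min_probes,repeat_threshold cascade thresholds.
#' @return one-row data.frame: probeset_id, category, gene_id,
#'   n_probes_matched, evidence.
#' @export
classify_probe_set <- function(probeset_id, probes, mrna_index, span_index,
                               genome_index, models, min_probes = 8L,
                               repeat_threshold = 10L) {
  rec <- function(category, gene = NA_character_, n = 0L, evidence = "") {
    data.frame(probeset_id = probeset_id, category = category,
               gene_id = gene, n_probes_matched = as.integer(n),
               evidence = evidence, stringsAsFactors = FALSE)
  }

  # stage 1: reference mRNA
  mrna <- match_probe_set(probes, mrna_index)
  tx_hit <- call_probeset_target(mrna$counts, min_probes)
  if (length(tx_hit)) {
    tx2gene <- setNames(models$gene_id, models$transcript_id)
    best <- tx_hit[which.max(mrna$counts[tx_hit])]
    return(rec("mRNA", gene = unname(tx2gene[best]),
               n = max(mrna$counts[tx_hit]),
               evidence = sprintf("matches transcript(s) %s",
                                  paste(tx_hit, collapse = ","))))
  }

  # repeat: per-probe genomic occurrence count (windows on either strand)
  gm <- match_probe_set(probes, genome_index)
  if (nrow(gm$matches)) {
    occ <- table(gm$matches$probe_index)
    if (any(occ > repeat_threshold))
      return(rec("repeat", n = length(unique(gm$matches$probe_index)),
                 evidence = sprintf("probe(s) with up to %d genomic occurrences",
                                    max(occ))))
  }

  # stage 2: gene spans
  sp <- match_probe_set(probes, span_index)
  span_hit <- call_probeset_target(sp$counts, min_probes)
  if (length(span_hit) > 1L)
    return(rec("ambiguous", n = max(sp$counts[span_hit]),
               evidence = sprintf("matches %d gene spans", length(span_hit))))
  if (length(span_hit) == 1L) {
    gene <- span_hit
    gmod <- models[models$gene_id == gene, , drop = FALSE]
    if (!nrow(gmod)) stopf("no transcript model for matched gene span '%s'", gene)
    strand <- gmod$strand[1]
    span_start <- min(gmod$start)
    m <- sp$matches[sp$matches$target == gene, , drop = FALSE]
    sense <- m$strand == strand
    if (!any(sense))
      return(rec("ambiguous", gene = gene, n = sp$counts[[gene]],
                 evidence = "antisense-only gene-span match"))
    ex <- gene_exon_intervals(models, gene)
    gstart <- span_start + m$offset
    gend <- gstart + attr_k(span_index)
    hits_exon <- vapply(seq_len(nrow(m)), function(i)
      any(gstart[i] < ex$end & gend[i] > ex$start), logical(1))
    if (any(hits_exon | !sense))
      return(rec("ambiguous", gene = gene, n = sp$counts[[gene]],
                 evidence = "matching probe overlaps exon or is antisense"))
    return(rec("intronic", gene = gene, n = sp$counts[[gene]],
               evidence = "all matching probes sense-strand, fully intronic"))
  }
  rec("unmapped", evidence = "no target reached the match threshold")
}

attr_k <- function(index) index$k

#' Annotate an entire probe-set collection
#'
#' Runs the classification cascade over every probe set and reports the
#' array's background intronic fraction (intronic / total over the probe
#' sets retained after removing an exclusion list, e.g. control probe
#' sets).
#'
#' @param probes long data.frame: probeset_id, probe_index, sequence.
#' @param transcript_seqs named character vector of RefSeq transcript
#'   (spliced, sense-strand) sequences; names are transcript ids present in
#'   \code{models}.
#' @param genome named character vector of chromosome sequences.
#' @param models transcript-model data.frame.
#' @param exclude probe-set ids excluded from the background fraction
#'   (still annotated).
#' @param min_probes,repeat_threshold cascade thresholds.
#' @return list: \code{annotation} (data.frame, one row per probe set) and
#'   \code{background} (list intronic, total, fraction).
#' @export
annotate_array <- function(probes, transcript_seqs, genome, models,
                           exclude = character(), min_probes = 8L,
                           repeat_threshold = 10L) {
  ids <- unique(probes$probeset_id)
  if (anyDuplicated(probes[, c("probeset_id", "probe_index")]))
    stopf("duplicate (probeset_id, probe_index) rows")
  k <- unique(nchar(probes$sequence))
  if (length(k) != 1L) stopf("all probes must share one length")

  mrna_index <- build_match_index(transcript_seqs, k = k)
  span_index <- build_match_index(gene_span_sequences(models, genome), k = k)
  genome_index <- build_match_index(drop_attributes(genome), k = k)

  ann <- do.call(rbind, lapply(ids, function(id) {
    classify_probe_set(id, probes$sequence[probes$probeset_id == id],
                       mrna_index, span_index, genome_index, models,
                       min_probes = min_probes,
                       repeat_threshold = repeat_threshold)
  }))
  kept <- ann[!ann$probeset_id %in% exclude, , drop = FALSE]
  background <- background_fraction(sum(kept$category == "intronic"), nrow(kept))
  list(annotation = ann, background = background)
}

drop_attributes <- function(x) {
  y <- as.vector(x)
  names(y) <- names(x)
  y
}

#' Background intronic fraction
#'
#' @param intronic,total counts of intronic and of all (non-excluded) probe
#'   sets on the array.
#' @return list intronic, total, fraction, percent (nearest percent).
#' @export
background_fraction <- function(intronic, total) {
  if (total < 0 || intronic < 0 || intronic > total)
    stopf("need 0 <= intronic <= total")
  frac <- if (total == 0) NA_real_ else intronic / total
  list(intronic = as.integer(intronic), total = as.integer(total),
       fraction = frac, percent = if (is.na(frac)) NA_real_ else round(100 * frac))
}
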