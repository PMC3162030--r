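#' Design probe sets with known classes and draw per-gene ground truth
#'
#' Creates probe sets of 11 distinct 25-mers each, per requested class:
#' \describe{
#'   \item{exonic}{substrings of the spliced (sense) mRNA sequence;}
#'   \item{intronic}{sense-strand sequence fully inside an intron;}
#'   \item{boundary}{sense-strand sequence straddling an exon/intron
#'     junction;}
#'   \item{repeat}{25-mers from a 35-bp block planted at
#'     \code{repeat_copies} genomic locations;}
#'   \item{antisense}{reverse complement of intronic sense sequence.}
#' }
#' Alongside the probes, the generative per-gene parameters (total
#' expression and unspliced fraction per group, selective/signature gene
#' identities) are drawn, so that downstream simulators and tests share one
#' ground truth.
#'
#' @param models transcript-model data.frame from [generate_gene_models()].
#' @param genome genome from [generate_gene_models()] (carries the planted
#'   repeat blocks as an attribute).
#' @param config a [sim_config()] object.
#' @return list with \code{probes} (data.frame probeset_id, probe_index,
#'   sequence), \code{probesets} (probeset_id, class, gene_id) and
#'   \code{truth} (list of class \code{sim_truth}).
#' @export
design_probe_sets <- function(models, genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n_probes <- 11L
  k <- 25L

  spliced <- spliced_sequences(models, genome)
  spans <- gene_spans(models)
  gene_ids <- spans$gene_id
  tx_of_gene <- setNames(models$transcript_id[!duplicated(models$gene_id)],
                         models$gene_id[!duplicated(models$gene_id)])
  intron_tab <- lapply(setNames(gene_ids, gene_ids),
                       function(g) gene_introns(models, g))
  has_intron <- vapply(intron_tab, nrow, 0L) > 0L
  intron_genes <- gene_ids[has_intron]

  cyc <- function(pool, n, what) {
    if (!length(pool)) stopf("no gene eligible to host %s probe sets", what)
    pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
  }
  pick_starts <- function(lo, hi, n, gene, what) {
    if (hi - lo + 1L < n)
      stopf("gene '%s' too short to host %d %s probes", gene, n, what)
    sort(sample(seq(lo, hi), n))
  }

  rows <- list()
  sets <- list()
  add_set <- function(id, class, gene, seqs) {
    if (anyDuplicated(seqs))
      stopf("duplicate 25-mers drawn for probe set '%s'", id)
    stopifnot(all(nchar(seqs) == k), length(seqs) == n_probes)
    rows[[length(rows) + 1L]] <<- data.frame(
      probeset_id = id, probe_index = seq_along(seqs), sequence = seqs,
      stringsAsFactors = FALSE)
    sets[[length(sets) + 1L]] <<- data.frame(
      probeset_id = id, class = class, gene_id = gene %||% NA_character_,
      stringsAsFactors = FALSE)
  }

  # exonic: 25-mers of the mature mRNA (may straddle exon-exon junctions)
  for (i in seq_len(n_probesets_of(config, "exonic"))) {
    g <- cyc(gene_ids, i, "exonic")[i]
    mrna <- spliced[[tx_of_gene[[g]]]]
    st <- pick_starts(1L, nchar(mrna) - k + 1L, n_probes, g, "exonic")
    add_set(sprintf("ps_ex_%03d", i), "exonic", g, substring(mrna, st, st + k - 1L))
  }

  # sense-strand genomic 25-mers fully inside the widest intron
  intronic_seqs <- function(g, n, avoid = NULL) {
    iv <- intron_tab[[g]]
    iv <- iv[which.max(iv$end - iv$start), ]
    st <- pick_starts(iv$start, iv$end - k, n, g, "intronic")
    s <- substring(genome[["chr1"]], st + 1L, st + k)
    if (spans$strand[spans$gene_id == g] == "-") s <- revcomp(s)
    s
  }
  for (i in seq_len(n_probesets_of(config, "intronic"))) {
    g <- cyc(intron_genes, i, "intronic")[i]
    add_set(sprintf("ps_in_%03d", i), "intronic", g, intronic_seqs(g, n_probes))
  }

  # straddling the first exon/intron junction (>=1 base on each side)
  for (i in seq_len(n_probesets_of(config, "boundary"))) {
    g <- cyc(intron_genes, i, "boundary")[i]
    j <- intron_tab[[g]]$start[1]
    st <- pick_starts(j - k + 1L, j - 1L, n_probes, g, "boundary")
    s <- substring(genome[["chr1"]], st + 1L, st + k)
    if (spans$strand[spans$gene_id == g] == "-") s <- revcomp(s)
    add_set(sprintf("ps_bd_%03d", i), "boundary", g, s)
  }

  # 11 overlapping 25-mers of a planted multi-copy block
  rep_blocks <- attr(genome, "repeat_blocks")
  n_rep <- n_probesets_of(config, "repeat")
  if (n_rep > 0L) {
    if (is.null(rep_blocks))
      stopf("repeat probe sets requested but no repeat blocks in genome")
    block_ids <- unique(rep_blocks$block_id)
    for (i in seq_len(n_rep)) {
      b <- rep_blocks$seq[match(block_ids[i], rep_blocks$block_id)]
      add_set(sprintf("ps_rp_%03d", i), "repeat", NULL,
              substring(b, seq_len(n_probes), seq_len(n_probes) + k - 1L))
    }
  }

  # reverse complement of intronic sense sequence
  for (i in seq_len(n_probesets_of(config, "antisense"))) {
    g <- cyc(rev(intron_genes), i, "antisense")[i]
    add_set(sprintf("ps_as_%03d", i), "antisense", g,
            revcomp(intronic_seqs(g, n_probes)))
  }

  probes <- do.call(rbind, rows)
  probesets <- do.call(rbind, sets)
  if (anyDuplicated(probesets$probeset_id)) stopf("duplicate probe-set ids")

  truth <- draw_gene_truth(gene_ids, probesets, config)
  truth$probesets <- probesets
  list(probes = probes, probesets = probesets, truth = truth)
}

# Per-gene generative parameters, drawn once and shared by the expression
# and qRT simulators.
draw_gene_truth <- function(gene_ids, probesets, config) {
  n <- length(gene_ids)
  baseline <- setNames(runif(n, config$baseline_log2_total[1],
                             config$baseline_log2_total[2]), gene_ids)
  intronic_probed <- unique(probesets$gene_id[probesets$class == "intronic"])
  intronic_probed <- intronic_probed[!is.na(intronic_probed)]

  truth <- list(design = config$design, baseline_log2 = baseline)

  if (config$design == "paired") {
    gn <- config$genotypes
    if (config$n_selective > length(intronic_probed))
      stopf("n_selective (%d) exceeds intronic-probed genes (%d)",
            config$n_selective, length(intronic_probed))
    selective <- intronic_probed[seq_len(config$n_selective)]
    rest <- setdiff(gene_ids, selective)
    if (config$n_mrna_up + config$n_mrna_down > length(rest))
      stopf("not enough genes left for planted mRNA shifts")
    mrna_up <- rest[seq_len(config$n_mrna_up)]
    mrna_down <- setdiff(rest, mrna_up)[seq_len(config$n_mrna_down)]

    log2_total <- cbind(baseline, baseline)
    colnames(log2_total) <- gn
    log2_total[mrna_up, 2] <- log2_total[mrna_up, 2] + config$mrna_log2fc
    log2_total[mrna_down, 2] <- log2_total[mrna_down, 2] - config$mrna_log2fc

    unspliced <- matrix(config$unspliced_fraction, n, 2,
                        dimnames = list(gene_ids, gn))
    unspliced[selective, 1] <- config$selective_unspliced[1]
    unspliced[selective, 2] <- config$selective_unspliced[2]

    truth$log2_total <- log2_total
    truth$unspliced <- unspliced
    truth$selective_genes <- selective
    truth$mrna_up_genes <- mrna_up
    truth$mrna_down_genes <- mrna_down
    truth$signature_probesets <- probesets$probeset_id[
      probesets$class == "intronic" & probesets$gene_id %in% selective]
  } else {
    ct <- names(config$celltypes)
    if (config$n_signature > length(intronic_probed))
      stopf("n_signature (%d) exceeds intronic-probed genes (%d)",
            config$n_signature, length(intronic_probed))
    signature <- intronic_probed[seq_len(config$n_signature)]
    profile <- matrix(rnorm(n * length(ct), 0, config$celltype_sd), n,
                      dimnames = list(gene_ids, ct))
    intr_profile <- matrix(rnorm(n * length(ct), 0, config$celltype_sd), n,
                           dimnames = list(gene_ids, ct))
    unspliced <- matrix(config$unspliced_fraction, n, length(ct),
                        dimnames = list(gene_ids, ct))
    if (length(signature)) {
      other <- setdiff(ct, config$target_celltype)
      unspliced[signature, other] <-
        runif(length(signature), config$signature_unspliced_other[1],
              config$signature_unspliced_other[2])
      unspliced[signature, config$target_celltype] <-
        runif(length(signature), config$signature_unspliced_target[1],
              config$signature_unspliced_target[2])
    }
    truth$profile <- profile
    truth$intron_profile <- intr_profile
    truth$unspliced <- unspliced
    truth$signature_genes <- signature
    truth$signature_probesets <- probesets$probeset_id[
      probesets$class == "intronic" & probesets$gene_id %in% signature]
  }
  class(truth) <- "sim_truth"
  truth
}
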