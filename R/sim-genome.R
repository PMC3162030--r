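#' Generate a synthetic genome and gene models
#'
#' Lays out \code{n_genes} non-overlapping genes with alternating exons and
#' introns along a single synthetic chromosome of uniform-random A/C/G/T
#' background, separated by random intergenic gaps. If repeat-class probe
#' sets are requested, 35-bp repeat blocks are planted in the intergenic
#' space, each copied to \code{repeat_copies} locations; their positions are
#' attached to the genome as \code{attr(genome, "repeat_blocks")}.
#'
#' @param config a [sim_config()] object.
#' @return list with elements \code{genome} (named character vector of
#'   chromosome sequences, with the repeat-block attribute) and
#'   \code{models} (transcript-model data.frame, one transcript per gene).
#' @export
generate_gene_models <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n <- config$n_genes
  runif_int <- function(k, rng) sample(seq(rng[1], rng[2]), k, replace = TRUE)

  genes <- lapply(seq_len(n), function(i) {
    n_ex <- runif_int(1L, config$exons_per_gene)
    ex_len <- runif_int(n_ex, config$exon_len)
    in_len <- if (n_ex > 1L) runif_int(n_ex - 1L, config$intron_len) else integer()
    list(id = sprintf("gene%03d", i),
         strand = sample(c("+", "-"), 1L),
         exon_len = ex_len, intron_len = in_len)
  })

  # repeat blocks to embed in intergenic gaps
  n_rep <- n_probesets_of(config, "repeat")
  rep_blocks <- if (n_rep > 0L) {
    lapply(seq_len(n_rep), function(i)
      list(block_id = sprintf("repblock%02d", i), seq = random_dna(35L)))
  } else list()
  copies <- unlist(lapply(rep_blocks, function(b)
    rep(b$block_id, config$repeat_copies)))
  gap_assign <- if (length(copies)) {
    split(copies, rep_len(seq_len(n + 1L), length(copies)))
  } else list()

  # assemble chromosome left to right, tracking offsets
  segs <- character(0)
  pos <- 0L
  rep_pos <- list()
  exon_rows <- list()
  block_seq <- setNames(vapply(rep_blocks, `[[`, "", "seq"),
                        vapply(rep_blocks, `[[`, "", "block_id"))
  emit_gap <- function(gap_idx) {
    ids <- gap_assign[[as.character(gap_idx)]] %||% character()
    gap_parts <- character(0)
    for (id in ids) {
      pad <- random_dna(runif_int(1L, config$intergenic_len))
      gap_parts <- c(gap_parts, pad)
      pos <<- pos + nchar(pad)
      rep_pos[[length(rep_pos) + 1L]] <<-
        data.frame(block_id = id, start = pos, end = pos + 35L)
      gap_parts <- c(gap_parts, block_seq[[id]])
      pos <<- pos + 35L
    }
    pad <- random_dna(runif_int(1L, config$intergenic_len))
    pos <<- pos + nchar(pad)
    c(gap_parts, pad)
  }

  for (i in seq_len(n)) {
    segs <- c(segs, emit_gap(i))
    g <- genes[[i]]
    starts <- integer(length(g$exon_len))
    ends <- integer(length(g$exon_len))
    for (j in seq_along(g$exon_len)) {
      starts[j] <- pos
      pos <- pos + g$exon_len[j]
      ends[j] <- pos
      if (j < length(g$exon_len)) pos <- pos + g$intron_len[j]
    }
    exon_rows[[i]] <- data.frame(
      gene_id = g$id, transcript_id = paste0(g$id, ".t1"), chrom = "chr1",
      strand = g$strand, start = starts, end = ends, refseq = TRUE,
      stringsAsFactors = FALSE)
    segs <- c(segs, random_dna(pos - sum(nchar(segs))))
  }
  segs <- c(segs, emit_gap(n + 1L))

  chrom_seq <- paste(segs, collapse = "")
  stopifnot(nchar(chrom_seq) == pos)
  if (!is.null(config$genome_length) && pos > config$genome_length)
    stopf("infeasible config: %d genes need %d bp but genome_length is %d",
          n, pos, config$genome_length)

  genome <- c(chr1 = chrom_seq)
  attr(genome, "repeat_blocks") <- if (length(rep_pos)) {
    rp <- do.call(rbind, rep_pos)
    rp$seq <- block_seq[rp$block_id]
    rp
  } else NULL
  models <- validate_models(do.call(rbind, exon_rows))
  list(genome = genome, models = models)
}
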