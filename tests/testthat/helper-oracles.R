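# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately avoid the package's match index and tree
# code: matching goes through Biostrings::matchPattern sliding-window
# scans, clade detection through stats::cutree, and agglomeration through
# a naive O(n^3) loop.

# every perfect occurrence of `query` in `seqs` (named character), both strands
bf_scan <- function(query, seqs) {
  hits <- lapply(names(seqs), function(nm) {
    subj <- Biostrings::DNAString(seqs[[nm]])
    fwd <- Biostrings::start(Biostrings::matchPattern(query, subj))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
    rev <- Biostrings::start(Biostrings::matchPattern(rc, subj))
    rbind(
      if (length(fwd)) data.frame(target = nm, offset = fwd - 1L, strand = "+"),
      if (length(rev)) data.frame(target = nm, offset = rev - 1L, strand = "-"))
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(target = character(), offset = integer(),
                               strand = character()) else out
}

bf_count_probes <- function(probes, seqs) {
  per_target <- sapply(names(seqs), function(nm) {
    sum(vapply(probes, function(p) nrow(bf_scan(p, seqs[nm])) > 0, logical(1)))
  })
  per_target[per_target > 0]
}

# sliding-window reimplementation of the annotation cascade
bf_classify <- function(probes, transcript_seqs, genome, models,
                        min_probes = 8L, repeat_threshold = 10L) {
  tx_counts <- bf_count_probes(probes, transcript_seqs)
  tx_hit <- names(tx_counts)[tx_counts >= min_probes]
  if (length(tx_hit)) return("mRNA")
  occ <- vapply(probes, function(p) nrow(bf_scan(p, genome)), 0L)
  if (any(occ > repeat_threshold)) return("repeat")
  spans <- gene_spans(models)
  span_seqs <- gene_span_sequences(models, genome)
  sp_counts <- bf_count_probes(probes, span_seqs)
  sp_hit <- names(sp_counts)[sp_counts >= min_probes]
  if (length(sp_hit) > 1L) return("ambiguous")
  if (length(sp_hit) == 1L) {
    gene <- sp_hit
    strand <- spans$strand[spans$gene_id == gene]
    s0 <- spans$start[spans$gene_id == gene]
    intr <- gene_introns(models, gene)
    ok <- TRUE
    any_sense <- FALSE
    for (p in probes) {
      h <- bf_scan(p, span_seqs[gene])
      if (!nrow(h)) next
      for (i in seq_len(nrow(h))) {
        sense <- h$strand[i] == strand
        any_sense <- any_sense || sense
        g1 <- s0 + h$offset[i]
        g2 <- g1 + nchar(p)
        inside_intron <- any(g1 >= intr$start & g2 <= intr$end)
        if (!sense || !inside_intron) ok <- FALSE
      }
    }
    if (!any_sense) return("ambiguous")
    return(if (ok) "intronic" else "ambiguous")
  }
  "unmapped"
}

# clade criterion via exhaustive tree cutting
cutree_clade <- function(hc, targets) {
  n <- length(hc$labels)
  tset <- sort(unique(targets))
  for (k in seq_len(n)) {
    cl <- cutree(hc, k = k)
    for (g in unique(cl)) {
      if (identical(sort(names(cl)[cl == g]), tset)) return(TRUE)
    }
  }
  FALSE
}

# naive O(n^3) agglomerative clustering; returns the leaf-set partition
# after each merge plus the merge heights
naive_agglomerate <- function(d, method = "complete") {
  dm <- as.matrix(d)
  clusters <- as.list(colnames(dm))
  heights <- numeric(0)
  steps <- list()
  link <- function(ci, cj) {
    vals <- dm[ci, cj]
    switch(method, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1), length(clusters))) {
        h <- link(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    steps <- c(steps, list(merged))
  }
  list(heights = heights, steps = steps)
}

hclust_steps <- function(hc) {
  leafsets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leafsets[[i]] <- sort(unlist(lapply(kids, function(k)
      if (k < 0) hc$labels[-k] else leafsets[[k]])))
  }
  leafsets
}

# small paired-design simulation used across tests
small_paired_sim <- function(seed = 7, noise_sd = 0.1, n_selective = 3,
                             n_pairs = 4, ...) {
  cfg <- sim_config(
    n_genes = 12,
    n_probesets = c(exonic = 8, intronic = 8, boundary = 3, `repeat` = 2,
                    antisense = 3),
    n_selective = n_selective, n_pairs = n_pairs, noise_sd = noise_sd,
    seed = seed, ...)
  list(cfg = cfg, sim = simulate_dataset(cfg))
}

truth_annotation <- function(probesets) {
  data.frame(
    probeset_id = probesets$probeset_id,
    category = ifelse(probesets$class == "exonic", "mRNA", probesets$class),
    gene_id = probesets$gene_id, stringsAsFactors = FALSE)
}
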