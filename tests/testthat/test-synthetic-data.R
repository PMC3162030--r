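# Generator: gene models, probe classes, expression and Ct tables with
# known ground truth.

test_that("gene models: structure, determinism, feasibility", {
  cfg1 <- sim_config(n_genes = 1, exons_per_gene = c(1, 1), seed = 3)
  gm1 <- generate_gene_models(cfg1)
  expect_equal(nrow(gm1$models), 1L)
  expect_equal(nrow(gene_introns(gm1$models, gm1$models$gene_id[1])), 0L)

  cfg <- sim_config(n_genes = 50, seed = 7)
  a <- generate_gene_models(cfg)
  b <- generate_gene_models(cfg)
  expect_identical(a, b)

  # genes non-overlapping, introns flanked by exons
  sp <- gene_spans(a$models)
  sp <- sp[order(sp$start), ]
  expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  for (g in sp$gene_id[1:5]) {
    ex <- intronsig:::gene_exon_intervals(a$models, g)
    intr <- gene_introns(a$models, g)
    if (nrow(intr)) {
      expect_true(all(intr$start %in% ex$end))
      expect_true(all(intr$end %in% ex$start))
    }
  }

  expect_error(generate_gene_models(
    sim_config(n_genes = 20, genome_length = 1000, seed = 1)),
    "infeasible")
})

test_that("intron sequences are absent from spliced transcripts", {
  cfg <- sim_config(n_genes = 20, exons_per_gene = c(2, 5), seed = 11)
  gm <- generate_gene_models(cfg)
  tx <- spliced_sequences(gm$models, gm$genome)
  for (g in unique(gm$models$gene_id)) {
    intr <- gene_introns(gm$models, g)
    for (i in seq_len(nrow(intr))) {
      iseq <- substr(gm$genome[["chr1"]], intr$start[i] + 1, intr$end[i])
      expect_false(any(vapply(tx, function(t) grepl(iseq, t, fixed = TRUE),
                              logical(1))))
    }
  }
})

test_that("probe classes are what they claim to be", {
  s <- small_paired_sim(seed = 5)
  sim <- s$sim
  tx <- spliced_sequences(sim$models, sim$genome)
  probes_of <- function(class) {
    ids <- sim$probesets$probeset_id[sim$probesets$class == class]
    split(sim$probes$sequence[sim$probes$probeset_id %in% ids],
          sim$probes$probeset_id[sim$probes$probeset_id %in% ids])
  }
  in_any_tx <- function(p) any(vapply(tx, function(t)
    grepl(p, t, fixed = TRUE), logical(1)))

  for (ps in probes_of("exonic")) {
    gene <- sim$probesets$gene_id[match(names(ps), sim$probesets$probeset_id)]
    expect_true(all(vapply(ps, in_any_tx, logical(1))))
  }
  for (ps in probes_of("intronic"))
    expect_false(any(vapply(ps, in_any_tx, logical(1))))
  # intronic probes lie wholly within an intron on the coding strand
  for (id in names(probes_of("intronic"))) {
    gene <- sim$probesets$gene_id[sim$probesets$probeset_id == id]
    strand <- gene_spans(sim$models)$strand[gene_spans(sim$models)$gene_id == gene]
    intr <- gene_introns(sim$models, gene)
    for (p in sim$probes$sequence[sim$probes$probeset_id == id]) {
      gseq <- if (strand == "-") revcomp(p) else p
      hit <- bf_scan(gseq, sim$genome["chr1"])
      hit <- hit[hit$strand == "+", ]
      expect_true(nrow(hit) >= 1)
      expect_true(any(hit$offset >= intr$start & hit$offset + 25 <= intr$end))
    }
  }
  # repeat probes occur at more genomic windows than the repeat threshold
  for (ps in probes_of("repeat")) {
    occ <- vapply(ps, function(p) nrow(bf_scan(p, sim$genome["chr1"])), 0L)
    expect_true(all(occ > 10))
  }
  expect_equal(nrow(sim$probes), 11L * nrow(sim$probesets))
  expect_false(anyDuplicated(sim$probesets$probeset_id) > 0)
})

test_that("noise-free expression obeys the generative formula", {
  s <- small_paired_sim(seed = 9, noise_sd = 0, n_selective = 3,
                        pair_sd = 0)
  sim <- s$sim
  x <- SummarizedExperiment::assay(sim$expression, "exprs")
  meta <- as.data.frame(SummarizedExperiment::colData(sim$expression))
  wt <- meta$group == "WT"; het <- meta$group == "het"
  ps <- sim$probesets
  for (i in which(ps$class == "intronic")) {
    gene <- ps$gene_id[i]
    ratio <- 2^(mean(x[ps$probeset_id[i], wt]) - mean(x[ps$probeset_id[i], het]))
    if (gene %in% sim$truth$selective_genes) {
      expect_equal(ratio, 0.4 / 0.1, tolerance = 1e-12)
    } else {
      expect_equal(ratio, 1, tolerance = 1e-12)
    }
  }
  for (i in which(ps$class == "exonic")) {
    ratio <- 2^(mean(x[ps$probeset_id[i], wt]) - mean(x[ps$probeset_id[i], het]))
    expect_equal(ratio, 1, tolerance = 1e-12)
  }
})

test_that("unspliced fractions are recovered from simulated expression", {
  cfg <- sim_config(n_genes = 30, n_probesets = c(exonic = 30, intronic = 30),
                    n_pairs = 6, noise_sd = 0.1, seed = 21)
  sim <- simulate_dataset(cfg)
  est <- estimate_unspliced_fractions(sim$expression, sim$probesets)
  truth_u <- sim$truth$unspliced[est$gene_id, "WT"]
  expect_true(all(abs(est$unspliced_hat - truth_u) < 0.05))
})

test_that("Ct model: halving quantity adds one cycle, reference constant", {
  s <- small_paired_sim(seed = 13, qrt_noise_sd = 0)
  q <- s$sim$qrt
  ref <- q[q$gene == "Gapdh", ]
  expect_equal(length(unique(round(ref$ct, 9))), 1L)
  # exonic vs intronic of a non-selective gene: quantity scaled by u = 0.25
  g <- setdiff(unique(q$gene[q$amplicon_type == "intronic"]),
               c(s$sim$truth$selective_genes, "Gapdh"))[1]
  ct_ex <- q$ct[q$gene == g & q$amplicon_type == "exonic"][1]
  ct_in <- q$ct[q$gene == g & q$amplicon_type == "intronic"][1]
  expect_equal(ct_in - ct_ex, -log2(0.25), tolerance = 1e-9)
})

test_that("simulation outputs round-trip through their file formats", {
  s <- small_paired_sim(seed = 17)
  dir <- withr::local_tempdir()
  write_simulation(s$sim, dir)
  expect_identical(read_genome_fasta(file.path(dir, "genome.fasta")),
                   intronsig:::drop_attributes(s$sim$genome))
  m2 <- read_models_gtf(file.path(dir, "models.gtf"))
  expect_equal(m2[, c("gene_id", "chrom", "strand", "start", "end")],
               s$sim$models[, c("gene_id", "chrom", "strand", "start", "end")])
  se2 <- read_expression_set(file.path(dir, "expression_exprs.tsv"),
                             file.path(dir, "expression_calls.tsv"),
                             file.path(dir, "expression_samples.tsv"))
  expect_equal(SummarizedExperiment::assay(se2, "exprs"),
               SummarizedExperiment::assay(s$sim$expression, "exprs"),
               tolerance = 1e-8)
})
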