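# Signature selection, row normalization, correlation clustering, the
# clade criterion and the randomization null.

test_that("row normalization: closed form, constant rows, invariant", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = rnorm(3))
  expect_warning(z <- row_normalize(m), "constant")
  expect_equal(unname(z["a", ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
})

test_that("signature selection is a per-gene argmax", {
  set.seed(8)
  x <- matrix(rnorm(6 * 6, mean = 8), 6, 6,
              dimnames = list(paste0("ps", 1:6), paste0("s", 1:6)))
  x["ps1", ] <- 7.1; x["ps2", ] <- 6.2  # two intronic sets of gene g1
  ann <- data.frame(probeset_id = paste0("ps", 1:6),
                    category = c("intronic", "intronic", "intronic",
                                 "mRNA", "mRNA", "mRNA"),
                    gene_id = c("g1", "g1", "g2", "g1", "g1", "g3"))
  samples <- data.frame(group = rep(c("WT", "het"), each = 3))
  se <- expression_matrix(x, matrix("Present", 6, 6, dimnames = dimnames(x)),
                          samples)
  expect_warning(sel <- select_signature(se, ann, "intronic_top_expressed"),
                 "no eligible")
  expect_equal(sel$probeset_id[sel$gene_id == "g1"], "ps1")
  expect_equal(nrow(sel), 2L)  # one per gene with an intronic set

  sel2 <- suppressWarnings(
    select_signature(se, ann, "mrna_most_different", c("WT", "het")))
  # brute-force argmax over |group mean difference|
  diffs <- abs(rowMeans(x[4:5, 1:3]) - rowMeans(x[4:5, 4:6]))
  expect_equal(sel2$probeset_id[sel2$gene_id == "g1"],
               names(which.max(diffs)))
})

test_that("correlation dendrogram: identical samples, planted blocks, oracle", {
  set.seed(12)
  m <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 1]  # identical pair merges first at distance 0
  hc <- correlation_dendrogram(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_true(all(sort(hc$merge[1, ]) == c(-2, -1)))

  # two planted blocks are the two depth-1 subtrees
  blocks <- cbind(matrix(rnorm(40, sd = 0.01) + rep(c(1, -1), 20), 40, 2),
                  matrix(rnorm(40, sd = 0.01) + rep(c(-1, 1), 20), 40, 2))
  colnames(blocks) <- paste0("s", 1:4)
  hb <- correlation_dendrogram(blocks)
  top <- hclust_steps(hb)[[nrow(hb$merge) - 1]]
  expect_true(identical(top, c("s1", "s2")) || identical(top, c("s3", "s4")))

  # merge heights and compositions equal a naive O(n^3) agglomeration
  for (method in c("complete", "average", "single")) {
    m8 <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, letters[1:8]))
    d <- as.dist(1 - cor(m8))
    hc8 <- correlation_dendrogram(m8, linkage = method)
    oracle <- naive_agglomerate(d, method)
    expect_equal(hc8$height, oracle$heights, tolerance = 1e-12)
    expect_identical(hclust_steps(hc8), oracle$steps)
  }

  const <- m; const[, 3] <- 5
  expect_error(correlation_dendrogram(const), "s3")
})

test_that("Pearson distances are bounded and location-invariant", {
  set.seed(14)
  m <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("s", 1:6)))
  d <- 1 - cor(m)
  expect_true(all(d >= 0 & d <= 2))
  shifted <- m; shifted[, 3] <- shifted[, 3] + 100
  expect_equal(1 - cor(shifted), d, tolerance = 1e-9)
})

test_that("clade criterion matches exhaustive tree cutting", {
  set.seed(16)
  # 2 targets merging first among 6 samples
  m <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("s", 1:6)))
  m[, 2] <- m[, 1] + rnorm(30, sd = 0.01)
  hc <- correlation_dendrogram(m)
  expect_true(clean_separation(hc, c("s1", "s2")))
  # random trees vs the cutree oracle
  for (i in 1:25) {
    n <- sample(4:7, 1)
    mm <- matrix(rnorm(20 * n), 20, n, dimnames = list(NULL, paste0("s", 1:n)))
    hcr <- correlation_dendrogram(mm)
    tgt <- sample(colnames(mm), sample(n - 1, 1))
    expect_equal(clean_separation(hcr, tgt), cutree_clade(hcr, tgt))
  }
  expect_error(clean_separation(hc, character(0)), "non-empty")
  expect_error(clean_separation(hc, paste0("s", 1:6)), "every leaf")
  # invariance under leaf rotation: relabeling by reordering input columns
  perm <- c(4, 2, 6, 1, 3, 5)
  hcp <- correlation_dendrogram(m[, perm])
  expect_equal(clean_separation(hcp, c("s1", "s2")),
               clean_separation(hc, c("s1", "s2")))
})

test_that("randomization null: determinism, degenerate draw, calibration", {
  cfg <- sim_config(design = "celltype", n_genes = 40,
                    n_probesets = c(exonic = 40, intronic = 40),
                    n_signature = 15, noise_sd = 0.1, seed = 11)
  sim <- simulate_dataset(cfg)
  se <- sim$expression
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  targets <- colnames(se)[meta$group == "HSC"]
  sig <- sim$truth$signature_probesets
  m <- SummarizedExperiment::assay(se, "exprs")

  hc <- correlation_dendrogram(m[sig, ])
  expect_true(clean_separation(hc, targets))

  pool <- setdiff(sim$probesets$probeset_id[sim$probesets$class == "intronic"],
                  sig)
  r1 <- randomization_null(se, pool, k = 15, n_draws = 100, targets, seed = 3)
  r2 <- randomization_null(se, pool, k = 15, n_draws = 100, targets, seed = 3)
  expect_identical(r1$n_clean, r2$n_clean)
  expect_equal(r1$fraction_clean, r1$n_clean / r1$n_draws)
  # uninformative draws essentially never isolate the target pair
  expect_lte(r1$fraction_clean, 0.05)

  # k = pool size: every draw identical, fraction is 0 or 1
  rall <- randomization_null(se, pool[1:6], k = 6, n_draws = 20, targets, seed = 5)
  expect_true(rall$fraction_clean %in% c(0, 1))
  expect_error(randomization_null(se, pool[1:3], k = 10, n_draws = 5,
                                  targets, seed = 1), "smaller")
})

test_that("separation advantage disappears under random target labels", {
  cfg <- sim_config(design = "celltype", n_genes = 40,
                    n_probesets = c(exonic = 40, intronic = 40),
                    n_signature = 15, noise_sd = 0.1, seed = 19)
  sim <- simulate_dataset(cfg)
  se <- sim$expression
  m <- SummarizedExperiment::assay(se, "exprs")
  sig <- sim$truth$signature_probesets
  set.seed(4)
  hits <- vapply(1:20, function(i) {
    fake <- sample(colnames(se), 2)
    clean_separation(correlation_dendrogram(m[sig, ]), fake)
  }, logical(1))
  # the planted signature separates the true targets, not arbitrary pairs
  expect_lte(mean(hits), 0.25)
})

test_that("newick export round-trips through ape", {
  set.seed(20)
  m <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("s", 1:5)))
  hc <- correlation_dendrogram(m)
  nwk <- dendrogram_newick(hc)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, colnames(m))
  # clades in the newick tree match the hclust clades
  expect_true(ape::is.monophyletic(tr, hclust_steps(hc)[[1]]))
})
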