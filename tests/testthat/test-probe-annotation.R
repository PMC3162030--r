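# Exact-match index and the probe-set classification cascade.

test_that("match index agrees with a brute-force sliding-window scan", {
  set.seed(41)
  seqs <- c(s1 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""),
            s2 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""),
            tiny = "ACGT")  # shorter than k: indexed but never matched
  idx <- build_match_index(seqs, k = 25)
  # queries: planted forward, planted reverse-complement, random
  st <- sample(9000, 80)
  planted <- substring(seqs[["s1"]], st, st + 24)
  queries <- unique(c(planted[1:40], revcomp(planted[41:80]),
                      vapply(1:40, function(i)
                        paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                              collapse = ""), "")))
  for (q in queries) {
    got <- query_index(idx, q)
    got <- got[order(got$target, got$offset, got$strand), ]
    want <- bf_scan(q, seqs)
    want <- want[order(want$target, want$offset, want$strand), ]
    expect_equal(got[, c("target", "offset", "strand")],
                 want, ignore_attr = TRUE)
  }
})

test_that("single and reverse-complement occurrences are each one hit", {
  s <- c(t1 = paste(c(rep("A", 30), "CGTACGTTAGCCATGCAGTTACGTA", rep("G", 30)),
                    collapse = ""))
  idx <- build_match_index(s)
  probe <- "CGTACGTTAGCCATGCAGTTACGTA"
  hit <- query_index(idx, probe)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 30L)
  rc_hit <- query_index(idx, revcomp(probe))
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$offset, 30L)
})

test_that("per-target probe counts and the 8-of-11 match call", {
  s <- small_paired_sim(seed = 23)
  sim <- s$sim
  tx <- spliced_sequences(sim$models, sim$genome)
  idx <- build_match_index(tx)
  ex_id <- sim$probesets$probeset_id[sim$probesets$class == "exonic"][1]
  probes <- sim$probes$sequence[sim$probes$probeset_id == ex_id]
  m <- match_probe_set(probes, idx)
  # all 11 probes inside the gene's own transcript
  gene <- sim$probesets$gene_id[sim$probesets$probeset_id == ex_id]
  expect_equal(unname(m$counts[paste0(gene, ".t1")]), 11L)
  expect_equal(bf_count_probes(probes, tx), m$counts[m$counts > 0])

  expect_equal(call_probeset_target(c(a = 8L)), "a")
  expect_identical(call_probeset_target(c(a = 7L)), character(0))
  expect_setequal(call_probeset_target(c(a = 11L, b = 9L, c = 2L)), c("a", "b"))
})

test_that("classification cascade on constructed edge cases", {
  # one plus-strand gene: exon[0,100) intron[100,400) exon[400,500)
  set.seed(77)
  chr <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  genome <- c(chr1 = chr)
  models <- transcript_models(
    gene_id = "gA", transcript_id = "gA.t1", chrom = "chr1", strand = "+",
    start = c(0, 400), end = c(100, 500))
  tx <- spliced_sequences(models, genome)
  mk_idx <- function() list(
    mrna = build_match_index(tx),
    span = build_match_index(gene_span_sequences(models, genome)),
    genome = build_match_index(genome))
  ix <- mk_idx()
  classify <- function(probes)
    classify_probe_set("ps", probes, ix$mrna, ix$span, ix$genome, models)

  intron_probe <- function(start) substring(chr, start + 1, start + 25)
  # 11/11 sense probes inside the intron -> intronic
  rec <- classify(intron_probe(seq(110, 310, by = 20)))
  expect_equal(rec$category, "intronic")
  expect_equal(rec$gene_id, "gA")
  # 9/11 probes matching the spliced transcript -> mRNA (stage 1 fires)
  mrna_probes <- c(substring(tx, seq(1, 161, by = 20), seq(25, 185, by = 20)),
                   strrep("A", 25), strrep("C", 25))
  expect_equal(classify(mrna_probes)$category, "mRNA")
  # 10 intronic + 1 straddling the exon/intron junction -> ambiguous
  straddle <- substr(chr, 100 - 10 + 1, 100 - 10 + 25)
  expect_equal(classify(c(intron_probe(seq(110, 290, by = 20)), straddle))$category,
               "ambiguous")
  # antisense-only -> ambiguous
  expect_equal(classify(revcomp(intron_probe(seq(110, 310, by = 20))))$category,
               "ambiguous")
  # nothing matched -> unmapped
  expect_equal(classify(vapply(1:11, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), ""))$category,
    "unmapped")
})

test_that("category is invariant under probe order permutation", {
  s <- small_paired_sim(seed = 29)
  sim <- s$sim
  tx <- spliced_sequences(sim$models, sim$genome)
  mrna_idx <- build_match_index(tx)
  span_idx <- build_match_index(gene_span_sequences(sim$models, sim$genome))
  gen_idx <- build_match_index(intronsig:::drop_attributes(sim$genome))
  set.seed(1)
  for (id in sample(sim$probesets$probeset_id, 6)) {
    probes <- sim$probes$sequence[sim$probes$probeset_id == id]
    a <- classify_probe_set(id, probes, mrna_idx, span_idx, gen_idx, sim$models)
    b <- classify_probe_set(id, sample(probes), mrna_idx, span_idx, gen_idx,
                            sim$models)
    expect_equal(a$category, b$category)
  }
})

test_that("annotation matches generator truth and the brute-force classifier", {
  s <- small_paired_sim(seed = 31)
  sim <- s$sim
  tx <- spliced_sequences(sim$models, sim$genome)
  ann <- annotate_array(sim$probes, tx, sim$genome, sim$models)
  truth_cat <- c(exonic = "mRNA", intronic = "intronic", boundary = "ambiguous",
                 `repeat` = "repeat", antisense = "ambiguous")
  got <- ann$annotation$category[match(sim$probesets$probeset_id,
                                       ann$annotation$probeset_id)]
  expect_equal(got, unname(truth_cat[sim$probesets$class]))
  # brute-force sliding-window agreement on a subset
  for (id in sim$probesets$probeset_id[c(1, 9, 17, 20, 22)]) {
    probes <- sim$probes$sequence[sim$probes$probeset_id == id]
    expect_equal(ann$annotation$category[ann$annotation$probeset_id == id],
                 bf_classify(probes, tx, sim$genome["chr1"], sim$models))
  }
})

test_that("classification is strand-aware: flipping the genome preserves it", {
  s <- small_paired_sim(seed = 37)
  sim <- s$sim
  L <- nchar(sim$genome[["chr1"]])
  flipped_genome <- c(chr1 = revcomp(sim$genome[["chr1"]]))
  fm <- sim$models
  new_start <- L - fm$end
  fm$end <- L - fm$start
  fm$start <- new_start
  fm$strand <- ifelse(fm$strand == "+", "-", "+")
  fm <- intronsig:::validate_models(fm)
  tx0 <- spliced_sequences(sim$models, sim$genome)
  tx1 <- spliced_sequences(fm, flipped_genome)
  expect_equal(tx1[names(tx0)], tx0)  # mRNA is strand-intrinsic
  a0 <- annotate_array(sim$probes, tx0, sim$genome, sim$models)$annotation
  a1 <- annotate_array(sim$probes, tx1, flipped_genome, fm)$annotation
  expect_equal(a1$category[match(a0$probeset_id, a1$probeset_id)], a0$category)
})

test_that("background fraction respects the exclusion list", {
  expect_equal(background_fraction(6780, 45037)$percent, 15)
  s <- small_paired_sim(seed = 43)
  sim <- s$sim
  tx <- spliced_sequences(sim$models, sim$genome)
  full <- annotate_array(sim$probes, tx, sim$genome, sim$models)
  excl <- annotate_array(sim$probes, tx, sim$genome, sim$models,
                         exclude = sim$probesets$probeset_id[
                           sim$probesets$class == "intronic"])
  expect_equal(full$background$intronic, 8L)
  expect_equal(full$background$total, nrow(sim$probesets))
  expect_equal(excl$background$intronic, 0L)
  expect_equal(excl$background$total, nrow(sim$probesets) - 8L)
  dup <- rbind(sim$probes, sim$probes[1, ])
  expect_error(annotate_array(dup, tx, sim$genome, sim$models), "duplicate")
})
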