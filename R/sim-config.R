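#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generators ([generate_gene_models()], [design_probe_sets()],
#' [simulate_expression()], [simulate_qrt()]).
#'
#' Two experimental designs are supported:
#' \describe{
#'   \item{\code{design = "paired"}}{Two genotypes measured in matched pairs
#'     (e.g. wild-type and hemizygous littermates). A subset of genes
#'     (\code{n_selective}) has a different unspliced fraction between
#'     genotypes while total mRNA stays equal; optional blocks of genes with
#'     genuine total-mRNA shifts can be planted via \code{n_mrna_up} /
#'     \code{n_mrna_down}.}
#'   \item{\code{design = "celltype"}}{Multiple cell populations. A subset of
#'     genes (\code{n_signature}) carries a population-specific unspliced
#'     excess in \code{target_celltype}; for all other genes each target
#'     sample mimics the mRNA profile of a different mature population, so
#'     that only the planted signature can isolate the target samples.}
#' }
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_len,intron_len,intergenic_len base-pair ranges (min, max).
#' @param genome_length optional cap on total genome length; generation
#'   fails if the requested genes do not fit.
#' @param n_probesets named integer vector with counts for classes
#'   \code{exonic}, \code{intronic}, \code{boundary}, \code{repeat},
#'   \code{antisense}.
#' @param repeat_copies number of genomic copies planted for each
#'   repeat-class probe block (must exceed the annotation repeat threshold
#'   for repeat probe sets to be called).
#' @param design \code{"paired"} or \code{"celltype"}.
#' @param genotypes length-2 character vector (reference first) for the
#'   paired design.
#' @param n_pairs number of matched pairs (paired design).
#' @param n_replicates technical replicates per biological sample.
#' @param celltypes named integer vector of samples per cell type
#'   (celltype design).
#' @param target_celltype the population the planted signature isolates.
#' @param baseline_log2_total range of per-gene log2 total expression.
#' @param unspliced_fraction default fraction of transcripts left unspliced,
#'   in \[0,1\].
#' @param n_selective number of genes whose unspliced fraction differs
#'   between genotypes (paired design).
#' @param selective_unspliced length-2 numeric: unspliced fraction in the
#'   reference and in the second genotype for selective genes.
#' @param n_mrna_up,n_mrna_down genes with planted total-mRNA shifts in the
#'   second genotype relative to the reference.
#' @param mrna_log2fc magnitude (log2) of planted total-mRNA shifts.
#' @param n_signature number of signature genes (celltype design).
#' @param signature_unspliced_target,signature_unspliced_other ranges the
#'   per-gene unspliced fraction is drawn from for signature genes, in the
#'   target and in the other populations.
#' @param pair_sd standard deviation of the shared log2 pair effect.
#' @param celltype_sd standard deviation of per-(gene, population) log2
#'   profile effects (celltype design).
#' @param noise_sd measurement noise standard deviation on the log2 scale.
#' @param present_threshold log2 intensity below which a detection call is
#'   "Absent".
#' @param background_log2 mean log2 signal of probe sets that do not detect
#'   their gene's transcripts (antisense, repeat).
#' @param qrt_experiments,qrt_samples_per_group,qrt_intercept,qrt_noise_sd
#'   qRT-PCR simulation: number of independent experiments, samples per
#'   group per experiment, Ct value of a unit quantity, and Ct noise sd.
#' @param seed integer seed; fixed seed gives bit-identical outputs.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 20,
                       exons_per_gene = c(2L, 5L),
                       exon_len = c(100L, 300L),
                       intron_len = c(200L, 800L),
                       intergenic_len = c(200L, 500L),
                       genome_length = NULL,
                       n_probesets = c(exonic = 10L, intronic = 10L,
                                       boundary = 0L, `repeat` = 0L,
                                       antisense = 0L),
                       repeat_copies = 12L,
                       design = c("paired", "celltype"),
                       genotypes = c("WT", "het"),
                       n_pairs = 4L,
                       n_replicates = 1L,
                       celltypes = c(HSC = 2L, MPP = 2L, MEP = 2L,
                                     GMP = 2L, B = 2L, Mono = 2L),
                       target_celltype = "HSC",
                       baseline_log2_total = c(10, 14),
                       unspliced_fraction = 0.25,
                       n_selective = 0L,
                       selective_unspliced = c(0.4, 0.1),
                       n_mrna_up = 0L,
                       n_mrna_down = 0L,
                       mrna_log2fc = 1,
                       n_signature = 0L,
                       signature_unspliced_target = c(0.3, 0.9),
                       signature_unspliced_other = c(0.02, 0.08),
                       pair_sd = 0.25,
                       celltype_sd = 1,
                       noise_sd = 0.1,
                       present_threshold = log2(100),
                       background_log2 = 5,
                       qrt_experiments = 3L,
                       qrt_samples_per_group = 3L,
                       qrt_intercept = 30,
                       qrt_noise_sd = 0.1,
                       seed = 1L) {
  design <- match.arg(design)
  cfg <- list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    intergenic_len = as.integer(intergenic_len),
    genome_length = if (is.null(genome_length)) NULL else as.integer(genome_length),
    n_probesets = n_probesets, repeat_copies = as.integer(repeat_copies),
    design = design, genotypes = genotypes, n_pairs = as.integer(n_pairs),
    n_replicates = as.integer(n_replicates),
    celltypes = celltypes, target_celltype = target_celltype,
    baseline_log2_total = baseline_log2_total,
    unspliced_fraction = unspliced_fraction,
    n_selective = as.integer(n_selective),
    selective_unspliced = selective_unspliced,
    n_mrna_up = as.integer(n_mrna_up), n_mrna_down = as.integer(n_mrna_down),
    mrna_log2fc = mrna_log2fc,
    n_signature = as.integer(n_signature),
    signature_unspliced_target = signature_unspliced_target,
    signature_unspliced_other = signature_unspliced_other,
    pair_sd = pair_sd, celltype_sd = celltype_sd, noise_sd = noise_sd,
    present_threshold = present_threshold, background_log2 = background_log2,
    qrt_experiments = as.integer(qrt_experiments),
    qrt_samples_per_group = as.integer(qrt_samples_per_group),
    qrt_intercept = qrt_intercept, qrt_noise_sd = qrt_noise_sd,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

probe_classes <- c("exonic", "intronic", "boundary", "repeat", "antisense")

validate_sim_config <- function(cfg) {
  chk_range <- function(x, nm) {
    if (length(x) != 2L || any(x <= 0) || x[2] < x[1])
      stopf("'%s' must be a positive (min, max) range", nm)
  }
  if (cfg$n_genes < 1L) stopf("'n_genes' must be >= 1")
  chk_range(cfg$exons_per_gene, "exons_per_gene")
  chk_range(cfg$exon_len, "exon_len")
  chk_range(cfg$intron_len, "intron_len")
  chk_range(cfg$intergenic_len, "intergenic_len")
  miss <- setdiff(names(cfg$n_probesets), probe_classes)
  if (length(miss)) stopf("unknown probe-set class(es): %s", paste(miss, collapse = ", "))
  if (any(cfg$n_probesets < 0)) stopf("probe-set counts must be non-negative")
  fr <- c(cfg$unspliced_fraction, cfg$selective_unspliced,
          cfg$signature_unspliced_target, cfg$signature_unspliced_other)
  if (any(fr < 0 | fr > 1)) stopf("all unspliced fractions must lie in [0, 1]")
  if (any(c(cfg$pair_sd, cfg$celltype_sd, cfg$noise_sd, cfg$qrt_noise_sd) < 0))
    stopf("noise standard deviations must be non-negative")
  if (cfg$design == "paired") {
    if (length(cfg$genotypes) != 2L) stopf("'genotypes' must have length 2")
    if (cfg$n_pairs < 1L) stopf("'n_pairs' must be >= 1")
    if (cfg$n_selective + cfg$n_mrna_up + cfg$n_mrna_down > cfg$n_genes)
      stopf("selective + mRNA-shift genes exceed 'n_genes'")
  } else {
    if (is.null(names(cfg$celltypes)) || any(cfg$celltypes < 1))
      stopf("'celltypes' must be a named vector of positive sample counts")
    if (!cfg$target_celltype %in% names(cfg$celltypes))
      stopf("'target_celltype' (%s) not among celltypes", cfg$target_celltype)
    if (length(cfg$celltypes) < 3L)
      stopf("celltype design needs at least 3 populations")
    if (cfg$n_signature > cfg$n_genes) stopf("'n_signature' exceeds 'n_genes'")
  }
  if (cfg$n_replicates < 1L) stopf("'n_replicates' must be >= 1")
  invisible(cfg)
}

n_probesets_of <- function(cfg, class) {
  n <- cfg$n_probesets[class]
  if (is.na(n)) 0L else as.integer(n)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (", x$design, " design)\n", sep = "")
  cat("  genes:", x$n_genes, " exons/gene:", paste(x$exons_per_gene, collapse = "-"), "\n")
  cat("  probe sets:", paste(sprintf("%s=%d", names(x$n_probesets), x$n_probesets), collapse = " "), "\n")
  if (x$design == "paired") {
    cat("  groups:", paste(x$genotypes, collapse = " vs "), "pairs:", x$n_pairs,
        "selective genes:", x$n_selective, "\n")
  } else {
    cat("  celltypes:", paste(sprintf("%s=%d", names(x$celltypes), x$celltypes), collapse = " "),
        "target:", x$target_celltype, "signature genes:", x$n_signature, "\n")
  }
  cat("  noise sd:", x$noise_sd, " seed:", x$seed, "\n")
  invisible(x)
}
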