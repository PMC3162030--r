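#' Simulate qRT-PCR Ct tables from ground truth
#'
#' Ct values follow the ideal-efficiency amplification model
#' \code{Ct = intercept - log2(quantity) + noise}: each PCR cycle doubles
#' the template, so halving the starting quantity raises Ct by one cycle.
#' Exonic amplicons report the gene's total expression, intronic amplicons
#' the unspliced portion (total x unspliced fraction). A reference gene
#' (\code{Gapdh}) with constant quantity is always included for every
#' sample.
#'
#' @param design result of [design_probe_sets()] (carries the truth), or a
#'   \code{sim_truth} object directly.
#' @param config a [sim_config()] object.
#' @param genes genes to assay; default: all genes with an intronic probe
#'   set (those have both amplicon types defined).
#' @param reference_gene name of the constant reference gene.
#' @param reference_quantity its (arbitrary, constant) starting quantity.
#' @return data.frame with columns gene, amplicon_type, sample, group,
#'   experiment, ct.
#' @export
simulate_qrt <- function(design, config, genes = NULL,
                         reference_gene = "Gapdh",
                         reference_quantity = 1024) {
  validate_sim_config(config)
  truth <- if (inherits(design, "sim_truth")) design else design$truth
  set.seed(config$seed + 3L)

  groups <- if (config$design == "paired") config$genotypes else
    names(config$celltypes)
  if (is.null(genes)) {
    ps <- truth$probesets
    genes <- unique(ps$gene_id[ps$class == "intronic" & !is.na(ps$gene_id)])
  }
  if (!length(genes)) stopf("no genes to assay")

  quantity_of <- function(gene, group, type) {
    total <- if (config$design == "paired")
      2^truth$log2_total[gene, group]
    else
      2^(truth$baseline_log2[[gene]] + truth$profile[gene, group])
    q <- if (type == "exonic") total else total * truth$unspliced[gene, group]
    if (!is.finite(q) || q <= 0)
      stopf("nonpositive quantity for gene '%s' (%s, %s)", gene, group, type)
    q
  }

  grid <- expand.grid(
    experiment = seq_len(config$qrt_experiments),
    group = groups, rep = seq_len(config$qrt_samples_per_group),
    stringsAsFactors = FALSE)
  grid$sample <- sprintf("e%d_%s_%d", grid$experiment, grid$group, grid$rep)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tab <- rbind(
      do.call(rbind, lapply(genes, function(gene) {
        data.frame(gene = gene, amplicon_type = c("exonic", "intronic"),
                   quantity = c(quantity_of(gene, g$group, "exonic"),
                                quantity_of(gene, g$group, "intronic")),
                   stringsAsFactors = FALSE)
      })),
      data.frame(gene = reference_gene, amplicon_type = "exonic",
                 quantity = reference_quantity, stringsAsFactors = FALSE))
    data.frame(gene = tab$gene, amplicon_type = tab$amplicon_type,
               sample = g$sample, group = g$group, experiment = g$experiment,
               ct = config$qrt_intercept - log2(tab$quantity) +
                 rnorm(nrow(tab), 0, config$qrt_noise_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run every synthetic-data generator in sequence
#'
#' @param config a [sim_config()] object.
#' @return list with genome, models, probes, probesets, truth, expression
#'   (SummarizedExperiment) and qrt (Ct table, paired design only unless
#'   genes are intronic-probed).
#' @export
simulate_dataset <- function(config) {
  gm <- generate_gene_models(config)
  des <- design_probe_sets(gm$models, gm$genome, config)
  se <- simulate_expression(gm$models, des, config)
  qrt <- tryCatch(simulate_qrt(des, config), error = function(e) NULL)
  list(genome = gm$genome, models = gm$models, probes = des$probes,
       probesets = des$probesets, truth = des$truth, expression = se,
       qrt = qrt)
}
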