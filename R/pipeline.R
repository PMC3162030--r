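# End-to-end orchestration: simulate (or load) -> annotate -> filter ->
# paired DE -> category tally + enrichment -> signature clustering with
# randomization null -> qRT splicing ratios. Every stage output is written
# atomically; a provenance record captures seeds, versions and the config
# hash.

#' Pipeline configuration
#'
#' All of the analysis tunables surfaced in one declarative object:
#' minimum intensity log2(100), minimum IQR 0.5, p < 0.05, fold change >
#' 1.5, the 8-of-11 probe match threshold, the 15% array background (when
#' not recomputed), the randomization draw count and signature size.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param sim arguments for the paired-design [sim_config()] (list), or
#'   NULL to skip simulation (then \code{paths} must point at inputs).
#' @param celltype_sim arguments for the celltype-design [sim_config()]
#'   used by the clustering stage, or NULL to skip that stage.
#' @param paths optional named list of input files (genome, models_gtf,
#'   probes, exprs, calls, samples, ct) used when \code{sim} is NULL.
#' @param filter a [filter_config()].
#' @param min_probes,repeat_threshold annotation cascade thresholds.
#' @param background_fraction intronic background fraction for expected
#'   counts; NULL recomputes it from the annotation.
#' @param n_draws randomization draws for the clustering null.
#' @param signature_k random draw size; NULL uses the planted signature
#'   size.
#' @param linkage clustering linkage.
#' @param enrichment_direction which DE direction enters the enrichment
#'   test ("down", per the observation that intronic changes are
#'   down-regulated, or "both").
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 42L,
                            sim = list(n_genes = 30, n_probesets = c(exonic = 30, intronic = 30),
                                       n_pairs = 4, n_selective = 10, noise_sd = 0.1),
                            celltype_sim = list(n_genes = 40,
                                                n_probesets = c(exonic = 40, intronic = 40),
                                                n_signature = 15, noise_sd = 0.1),
                            paths = NULL,
                            filter = filter_config(),
                            min_probes = 8L, repeat_threshold = 10L,
                            background_fraction = NULL,
                            n_draws = 200L, signature_k = NULL,
                            linkage = "complete",
                            enrichment_direction = c("down", "both")) {
  cfg <- list(seed = as.integer(seed), sim = sim, celltype_sim = celltype_sim,
              paths = paths, filter = filter, min_probes = as.integer(min_probes),
              repeat_threshold = as.integer(repeat_threshold),
              background_fraction = background_fraction,
              n_draws = as.integer(n_draws), signature_k = signature_k,
              linkage = linkage,
              enrichment_direction = match.arg(enrichment_direction))
  if (is.null(cfg$sim) && is.null(cfg$paths))
    stopf("either 'sim' or 'paths' must be provided")
  if (!is.null(cfg$paths)) {
    need <- c("genome", "models_gtf", "probes", "exprs", "calls", "samples")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss)) stopf("paths missing: %s", paste(miss, collapse = ", "))
    absent <- !file.exists(unlist(cfg$paths))
    if (any(absent))
      stopf("input file(s) not found: %s",
            paste(unlist(cfg$paths)[absent], collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_config, raw$filter)
  if (!is.null(raw$sim$n_probesets))
    raw$sim$n_probesets <- unlist(raw$sim$n_probesets)
  if (!is.null(raw$celltype_sim$n_probesets))
    raw$celltype_sim$n_probesets <- unlist(raw$celltype_sim$n_probesets)
  do.call(pipeline_config, raw)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order and writes every stage output under
#' \code{outdir}: simulated inputs (or loaded files), the annotation table
#' with its background summary, the retained probe-set list, the DE table,
#' the category tally with expected intronic counts and enrichment test,
#' the signature clustering report (dendrogram in Newick plus the
#' randomization null), the qRT ratio/classification tables, and a
#' provenance JSON recording seeds, package and R versions and the config
#' hash. Reruns with the same config are byte-identical.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param outdir output directory, created if needed.
#' @return (invisibly) a list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  results <- list()

  # --- inputs: simulate or load -------------------------------------------
  if (!is.null(config$sim)) {
    sim_cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- stage("simulate", simulate_dataset(sim_cfg))
    stage("simulate", write_simulation(sim, file.path(outdir, "simulated")))
    genotypes <- sim_cfg$genotypes
  } else {
    sim <- stage("load", list(
      genome = read_genome_fasta(config$paths$genome),
      models = read_models_gtf(config$paths$models_gtf),
      probes = read_tsv(config$paths$probes),
      expression = read_expression_set(config$paths$exprs, config$paths$calls,
                                       config$paths$samples),
      qrt = if (!is.null(config$paths$ct)) read_tsv(config$paths$ct) else NULL))
    genotypes <- unique(samples_of(sim$expression)$group)
  }
  results$sim <- sim

  # --- annotation ----------------------------------------------------------
  ann <- stage("annotate", annotate_array(
    sim$probes, spliced_sequences(sim$models, sim$genome), sim$genome,
    sim$models, min_probes = config$min_probes,
    repeat_threshold = config$repeat_threshold))
  write_atomic(function(p) write_tsv(ann$annotation, p),
               file.path(outdir, "annotation.tsv"))
  results$annotation <- ann

  # --- filtering and paired DE --------------------------------------------
  se <- stage("filter", average_technical_replicates(sim$expression))
  retained <- stage("filter", filter_probe_sets(se, config$filter))
  write_atomic(function(p) writeLines(retained, p),
               file.path(outdir, "retained_probesets.txt"))
  de <- stage("de", paired_differential_expression(
    se, retained, genotypes[1], genotypes[2], config$filter))
  write_atomic(function(p) write_tsv(de, p), file.path(outdir, "de_table.tsv"))
  results$retained <- retained
  results$de <- de

  # --- tally and enrichment ------------------------------------------------
  bg <- if (is.null(config$background_fraction)) ann$background else {
    list(intronic = NA_integer_, total = NA_integer_,
         fraction = config$background_fraction,
         percent = round(100 * config$background_fraction))
  }
  tally <- stage("enrich", tally_categories(de, ann$annotation, background = bg))
  de_sub <- if (config$enrichment_direction == "down")
    de[de$direction == "down", , drop = FALSE] else de
  obs_intronic <- sum(ann$annotation$category[
    match(de_sub$probeset_id, ann$annotation$probeset_id)] == "intronic",
    na.rm = TRUE)
  enr <- if (nrow(de_sub) && !is.na(bg$intronic)) {
    stage("enrich", intronic_enrichment_test(
      obs_intronic, nrow(de_sub), bg$intronic, bg$total))
  } else NULL
  write_atomic(function(p) jsonlite::write_json(list(
    counts = as.data.frame(tally$counts),
    expected_intronic = tally$expected_intronic,
    background = bg,
    enrichment = if (!is.null(enr)) enr[c("statistic", "p_value",
                                          "observed_fraction",
                                          "background_fraction")]),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(outdir, "enrichment.json"))
  results$tally <- tally
  results$enrichment <- enr

  # --- signature clustering against the randomization null -----------------
  if (!is.null(config$celltype_sim)) {
    ct_cfg <- do.call(sim_config, c(config$celltype_sim,
                                    list(design = "celltype",
                                         seed = config$seed + 1000L)))
    ct_sim <- stage("cluster", simulate_dataset(ct_cfg))
    ct_se <- ct_sim$expression
    sig <- ct_sim$truth$signature_probesets
    meta <- samples_of(ct_se)
    targets <- colnames(ct_se)[meta$group == ct_cfg$target_celltype]
    m <- exprs_of(ct_se)
    hc <- stage("cluster", correlation_dendrogram(
      m[sig, , drop = FALSE], linkage = config$linkage))
    sep <- clean_separation(hc, targets)
    pool <- setdiff(
      ct_sim$probesets$probeset_id[ct_sim$probesets$class == "intronic"], sig)
    pool <- pool[rowMeans(m[pool, , drop = FALSE]) >= config$filter$min_log2_intensity]
    k <- config$signature_k %||% length(sig)
    rand <- stage("cluster", randomization_null(
      ct_se, pool, k = min(k, length(pool)), n_draws = config$n_draws,
      target_labels = targets, seed = config$seed + 2000L,
      linkage = config$linkage))
    write_atomic(function(p) writeLines(dendrogram_newick(hc), p),
                 file.path(outdir, "signature_dendrogram.nwk"))
    write_atomic(function(p) jsonlite::write_json(
      c(list(signature_clean_separation = sep), unclass(rand)),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(outdir, "randomization.json"))
    results$clustering <- list(dendrogram = hc, clean = sep, null = rand)
  }

  # --- qRT splicing ratios -------------------------------------------------
  if (!is.null(sim$qrt)) {
    q <- stage("ratios", ddct_quantify(sim$qrt, calibrator_group = genotypes[1]))
    rs <- stage("ratios", genotype_ratio_summary(q, genotypes[1], genotypes[2]))
    rs$splicing_class <- classify_splicing_change(rs$mrna_ratio, rs$intronic_ratio)
    write_atomic(function(p) write_tsv(rs, p), file.path(outdir, "splicing_ratios.tsv"))
    results$ratios <- rs
  }

  # --- provenance ----------------------------------------------------------
  cfg_file <- file.path(outdir, "config.json")
  write_atomic(function(p) jsonlite::write_json(
    serialize_config(config), p, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    cfg_file)
  write_atomic(function(p) jsonlite::write_json(list(
    package = "intronsig",
    package_version = as.character(utils::packageVersion("intronsig")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file))),
    p, auto_unbox = TRUE, pretty = TRUE),
    file.path(outdir, "provenance.json"))
  invisible(results)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$filter <- unclass(cfg$filter)
  cfg
}
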