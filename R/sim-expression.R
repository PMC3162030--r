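#' Construct an expression container
#'
#' Bundles log2 intensities, Present/Absent detection calls and sample
#' metadata into a [SummarizedExperiment::SummarizedExperiment] with assays
#' \code{"exprs"} and \code{"calls"}.
#'
#' @param exprs numeric matrix, probe sets x samples.
#' @param calls character matrix of "Present"/"Absent"/"Marginal", same
#'   dimensions as \code{exprs}.
#' @param samples data.frame of sample metadata, one row per column of
#'   \code{exprs}; must contain a \code{group} column; optional columns
#'   \code{sample} (biological sample id), \code{pair}, \code{replicate},
#'   \code{cell_type}.
#' @return a SummarizedExperiment.
#' @export
expression_matrix <- function(exprs, calls, samples) {
  if (!all(dim(exprs) == dim(calls)))
    stopf("'exprs' and 'calls' must have identical dimensions")
  if (nrow(samples) != ncol(exprs))
    stopf("'samples' must have one row per expression column")
  if (is.null(samples$group)) stopf("'samples' must contain a 'group' column")
  bad <- setdiff(unique(as.vector(calls)), c("Present", "Absent", "Marginal"))
  if (length(bad)) stopf("invalid detection call(s): %s", paste(bad, collapse = ", "))
  if (is.null(samples$sample)) samples$sample <- colnames(exprs)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs, calls = calls),
    colData = S4Vectors::DataFrame(samples, row.names = colnames(exprs)))
}

exprs_of <- function(se) SummarizedExperiment::assay(se, "exprs")
calls_of <- function(se) SummarizedExperiment::assay(se, "calls")
samples_of <- function(se) as.data.frame(SummarizedExperiment::colData(se))

#' Simulate a probe-set expression matrix from ground truth
#'
#' Mean log2 signal of an exonic probe set is the gene's log2 total
#' expression; an intronic or boundary probe set reads the unspliced
#' fraction of it (\code{log2(total * unspliced_fraction)}); antisense and
#' repeat probe sets read a flat background. Gaussian noise (sd
#' \code{noise_sd}) is added on the log2 scale and detection calls are
#' thresholded at \code{present_threshold}.
#'
#' In the paired design, both genotypes of a pair share a per-(gene, pair)
#' random effect. In the celltype design, each sample of the target
#' population mimics the mRNA profile of a different mature population
#' (round-robin decoy profiles), while signature genes' intronic signal
#' follows the sample's true population - so only the planted signature
#' carries information that isolates the target samples.
#'
#' @param models transcript-model data.frame (for probe-set/gene linkage).
#' @param design result of [design_probe_sets()] (probes + truth).
#' @param config a [sim_config()] object.
#' @return a SummarizedExperiment (see [expression_matrix()]).
#' @export
simulate_expression <- function(models, design, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  truth <- design$truth
  ps <- design$probesets

  if (config$design == "paired") {
    gn <- config$genotypes
    pairs <- seq_len(config$n_pairs)
    bio <- expand.grid(pair = pairs, group = gn, stringsAsFactors = FALSE)
    bio$sample <- sprintf("%s_p%02d", bio$group, bio$pair)
    # per-(gene, pair) effect: biological variation shared by both
    # genotypes of a pair and by all probe sets of a gene
    n_genes <- nrow(truth$log2_total)
    pair_eff <- matrix(rnorm(n_genes * length(pairs), 0, config$pair_sd),
                       n_genes, length(pairs))
    mu <- matrix(NA_real_, nrow(ps), nrow(bio),
                 dimnames = list(ps$probeset_id, bio$sample))
    gi <- match(ps$gene_id, rownames(truth$log2_total))
    for (j in seq_len(nrow(bio))) {
      gc <- match(bio$group[j], colnames(truth$log2_total))
      base <- ifelse(ps$class %in% c("exonic", "intronic", "boundary"),
                     truth$log2_total[cbind(gi, gc)], config$background_log2)
      u_term <- ifelse(ps$class %in% c("intronic", "boundary"),
                       log2(truth$unspliced[cbind(gi, gc)]), 0)
      pe <- pair_eff[cbind(gi, bio$pair[j])]
      pe[is.na(pe)] <- 0
      u_term[is.na(u_term)] <- 0
      base[is.na(base)] <- config$background_log2
      mu[, j] <- base + u_term + pe
    }
    meta_extra <- data.frame(pair = bio$pair, cell_type = NA_character_)
  } else {
    ct <- names(config$celltypes)
    other <- setdiff(ct, config$target_celltype)
    bio <- do.call(rbind, lapply(ct, function(c0) {
      data.frame(group = c0,
                 sample = sprintf("%s_s%02d", c0, seq_len(config$celltypes[[c0]])),
                 stringsAsFactors = FALSE)
    }))
    is_target <- bio$group == config$target_celltype
    bio$profile <- bio$group
    bio$profile[is_target] <- other[((seq_len(sum(is_target)) - 1L) %% length(other)) + 1L]
    sig <- ps$gene_id %in% truth$signature_genes & ps$class == "intronic"
    mu <- matrix(NA_real_, nrow(ps), nrow(bio),
                 dimnames = list(ps$probeset_id, bio$sample))
    gi <- match(ps$gene_id, rownames(truth$profile))
    for (j in seq_len(nrow(bio))) {
      pc <- match(bio$profile[j], colnames(truth$profile))
      tc <- match(bio$group[j], colnames(truth$profile))
      base <- ifelse(ps$class %in% c("exonic", "intronic", "boundary"),
                     truth$baseline_log2[ps$gene_id] + truth$profile[cbind(gi, pc)],
                     config$background_log2)
      u_term <- ifelse(ps$class %in% c("intronic", "boundary"),
                       log2(truth$unspliced[cbind(gi, tc)]), 0)
      # the signature's intronic signal tracks the true population
      base[sig] <- truth$baseline_log2[ps$gene_id[sig]] +
        truth$intron_profile[cbind(gi[sig], tc)]
      u_term[is.na(u_term)] <- 0
      base[is.na(base)] <- config$background_log2
      mu[, j] <- base + u_term
    }
    meta_extra <- data.frame(pair = NA_integer_, cell_type = bio$group)
  }

  # technical replicates: same mean, independent noise
  reps <- seq_len(config$n_replicates)
  col_idx <- rep(seq_len(nrow(bio)), each = length(reps))
  exprs <- mu[, col_idx, drop = FALSE] +
    matrix(rnorm(nrow(mu) * length(col_idx), 0, config$noise_sd),
           nrow(mu), length(col_idx))
  colnames(exprs) <- sprintf("%s_r%d", bio$sample[col_idx],
                             rep(reps, nrow(bio)))
  calls <- ifelse(exprs >= config$present_threshold, "Present", "Absent")
  samples <- data.frame(
    sample = bio$sample[col_idx], group = bio$group[col_idx],
    meta_extra[col_idx, , drop = FALSE],
    replicate = rep(reps, nrow(bio)), stringsAsFactors = FALSE)
  expression_matrix(exprs, calls, samples)
}

#' Recover per-gene unspliced fractions from an expression matrix
#'
#' For genes carrying both an exonic and an intronic probe set, estimates
#' the unspliced fraction as \code{2^(mean intronic - mean exonic)} log2
#' signal, the inverse of the generative model; used for parameter-recovery
#' checks and as a simple summary on real annotations.
#'
#' @param se expression SummarizedExperiment.
#' @param probesets data.frame with columns probeset_id, class, gene_id
#'   (generator truth or an annotation table recoded to these columns).
#' @param samples optional character vector of sample columns to use.
#' @return data.frame gene_id, unspliced_hat.
#' @export
estimate_unspliced_fractions <- function(se, probesets, samples = NULL) {
  x <- exprs_of(se)
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  m <- rowMeans(x)
  res <- lapply(split(probesets, probesets$gene_id), function(p) {
    ex <- p$probeset_id[p$class %in% c("exonic", "mRNA")]
    intr <- p$probeset_id[p$class == "intronic"]
    ex <- intersect(ex, names(m)); intr <- intersect(intr, names(m))
    if (!length(ex) || !length(intr)) return(NULL)
    data.frame(gene_id = p$gene_id[1],
               unspliced_hat = 2^(mean(m[intr]) - mean(m[ex])))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
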