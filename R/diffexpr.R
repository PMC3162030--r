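# Filtering and paired differential expression on normalized log2
# intensities with Present/Absent detection calls.

#' Filter configuration
#'
#' Cut-offs for probe-set filtering and differential-expression calling:
#' minimum log2 intensity log2(100), minimum interquartile range 0.5,
#' paired t-test p < 0.05 and linear fold change > 1.5.
#'
#' @param min_log2_intensity probe sets with all intensities strictly below
#'   this are excluded.
#' @param min_iqr probe sets with IQR strictly below this are excluded.
#' @param p_threshold p-value cut-off (strict \code{<}).
#' @param fc_threshold linear fold-change cut-off (strict \code{>}).
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_log2_intensity = log2(100), min_iqr = 0.5,
                          p_threshold = 0.05, fc_threshold = 1.5) {
  cfg <- list(min_log2_intensity = min_log2_intensity, min_iqr = min_iqr,
              p_threshold = p_threshold, fc_threshold = fc_threshold)
  if (any(unlist(cfg) <= 0)) stopf("all filter thresholds must be positive")
  class(cfg) <- "filter_config"
  cfg
}

#' Average technical replicates into one column per biological sample
#'
#' Log2 intensities of technical replicates are averaged (arithmetic mean
#' on the log2 scale) before filtering. A merged detection call is "Absent"
#' only if all replicates are "Absent"; otherwise "Present" if any
#' replicate is, else "Marginal".
#'
#' @param se expression SummarizedExperiment whose colData has columns
#'   \code{sample} (biological id) and \code{replicate}.
#' @return SummarizedExperiment with one column per biological sample.
#' @export
average_technical_replicates <- function(se) {
  meta <- samples_of(se)
  if (is.null(meta$sample)) stopf("colData must contain a 'sample' column")
  groups <- split(seq_len(ncol(se)), meta$sample)
  for (idx in groups) {
    for (col in intersect(c("group", "pair", "cell_type"), names(meta))) {
      if (length(unique(meta[[col]][idx])) > 1L)
        stopf("replicate group '%s' spans several biological samples (%s differs)",
              meta$sample[idx[1]], col)
    }
  }
  groups <- groups[unique(meta$sample)]  # keep input order
  x <- exprs_of(se)
  cl <- calls_of(se)
  exprs <- do.call(cbind, lapply(groups, function(i)
    rowMeans(x[, i, drop = FALSE])))
  calls <- do.call(cbind, lapply(groups, function(i) {
    sub <- cl[, i, drop = FALSE]
    out <- rep("Marginal", nrow(sub))
    out[rowSums(sub == "Absent") == ncol(sub)] <- "Absent"
    out[rowSums(sub == "Present") > 0L] <- "Present"
    out
  }))
  dimnames(exprs) <- dimnames(calls) <- list(rownames(se), names(groups))
  first <- vapply(groups, `[`, 0L, 1L)
  samples <- meta[first, setdiff(names(meta), "replicate"), drop = FALSE]
  samples$replicate <- NULL
  rownames(samples) <- NULL
  expression_matrix(exprs, calls, samples)
}

#' Filter probe sets before differential-expression testing
#'
#' A probe set is excluded when all samples are called "Absent", when all
#' intensities lie strictly below \code{min_log2_intensity}, or when the
#' interquartile range across samples is strictly below \code{min_iqr}
#' (linear-interpolation quantiles, the stats default).
#'
#' @param se expression SummarizedExperiment (replicates already averaged).
#' @param config a [filter_config()].
#' @return character vector of retained probe-set ids.
#' @export
filter_probe_sets <- function(se, config = filter_config()) {
  if (nrow(se) == 0L || ncol(se) == 0L) stopf("empty expression matrix")
  x <- exprs_of(se)
  cl <- calls_of(se)
  all_absent <- rowSums(cl == "Absent") == ncol(cl)
  all_low <- rowSums(x < config$min_log2_intensity) == ncol(x)
  iqr <- apply(x, 1L, IQR)
  low_iqr <- iqr < config$min_iqr
  rownames(se)[!(all_absent | all_low | low_iqr)]
}

#' Paired differential expression between two groups
#'
#' Two-sided paired Student t-tests on log2 intensities over matched pairs;
#' fold change is \code{2^|mean paired log2 difference|} with the direction
#' given by the sign of the mean difference (\code{group_b} relative to
#' \code{group_a}, i.e. mutant relative to wild-type). Probe sets with
#' p-value below \code{p_threshold} and fold change above
#' \code{fc_threshold} (both strict) are reported. When all paired
#' differences are identical the t statistic is undefined: such records are
#' flagged \code{degenerate} and emitted only if the fold-change criterion
#' holds.
#'
#' @param se averaged expression SummarizedExperiment whose colData has
#'   \code{group} and \code{pair}.
#' @param retained probe-set ids to test (from [filter_probe_sets()]).
#' @param group_a reference group (wild-type).
#' @param group_b comparison group (mutant).
#' @param config a [filter_config()].
#' @return data.frame: probeset_id, direction ("up"/"down"), p_value,
#'   fold_change, mean_log2_a, mean_log2_b, degenerate.
#' @export
paired_differential_expression <- function(se, retained, group_a, group_b,
                                           config = filter_config()) {
  meta <- samples_of(se)
  if (is.null(meta$pair)) stopf("colData must contain a 'pair' column")
  a <- which(meta$group == group_a)
  b <- which(meta$group == group_b)
  if (!length(a) || !length(b))
    stopf("group '%s' or '%s' absent from the data", group_a, group_b)
  pairs <- intersect(meta$pair[a], meta$pair[b])
  if (length(meta$pair[a]) != length(pairs) || length(meta$pair[b]) != length(pairs))
    stopf("groups must have equal pair counts with matching pair ids")
  if (length(pairs) < 2L) stopf("need at least 2 pairs for a paired t-test")
  a <- a[match(pairs, meta$pair[a])]
  b <- b[match(pairs, meta$pair[b])]

  x <- exprs_of(se)[retained, , drop = FALSE]
  rows <- lapply(seq_len(nrow(x)), function(i) {
    d <- x[i, b] - x[i, a]
    md <- mean(d)
    fc <- 2^abs(md)
    degenerate <- sd(d) == 0
    p <- if (degenerate) NA_real_ else t.test(d)$p.value
    keep <- fc > config$fc_threshold &&
      (degenerate || (!is.na(p) && p < config$p_threshold))
    if (!keep) return(NULL)
    data.frame(probeset_id = rownames(x)[i],
               direction = if (md > 0) "up" else "down",
               p_value = p, fold_change = fc,
               mean_log2_a = mean(x[i, a]), mean_log2_b = mean(x[i, b]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(probeset_id = character(), direction = character(),
                      p_value = numeric(), fold_change = numeric(),
                      mean_log2_a = numeric(), mean_log2_b = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
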