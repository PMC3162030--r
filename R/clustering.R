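# Signature selection, correlation-based hierarchical clustering, the
# clade ("clean separation") criterion and its randomization null.

#' Select one probe set per gene for a clustering signature
#'
#' Two modes: \code{"intronic_top_expressed"} keeps, per gene, the intronic
#' probe set with the highest mean expression (avoids overweighting genes
#' detected by several intronic probe sets); \code{"mrna_most_different"}
#' keeps, per gene, the mRNA probe set with the largest absolute mean
#' difference in a reference contrast.
#'
#' @param se expression SummarizedExperiment.
#' @param annotation data.frame with probeset_id, category, gene_id.
#' @param mode selection mode (see above).
#' @param reference_contrast length-2 character vector of group labels
#'   defining the contrast (required for \code{"mrna_most_different"}).
#' @return data.frame gene_id, probeset_id. Genes with no eligible probe
#'   set are omitted with a warning.
#' @export
select_signature <- function(se, annotation,
                             mode = c("intronic_top_expressed",
                                      "mrna_most_different"),
                             reference_contrast = NULL) {
  mode <- match.arg(mode)
  x <- exprs_of(se)
  want <- if (mode == "intronic_top_expressed") "intronic" else "mRNA"
  ann <- annotation[!is.na(annotation$gene_id), , drop = FALSE]
  score <- if (mode == "intronic_top_expressed") {
    rowMeans(x)
  } else {
    if (is.null(reference_contrast) || length(reference_contrast) != 2L)
      stopf("'mrna_most_different' needs a length-2 reference_contrast")
    meta <- samples_of(se)
    a <- meta$group == reference_contrast[1]
    b <- meta$group == reference_contrast[2]
    if (!any(a) || !any(b)) stopf("reference_contrast groups not in the data")
    abs(rowMeans(x[, a, drop = FALSE]) - rowMeans(x[, b, drop = FALSE]))
  }
  res <- lapply(split(ann, ann$gene_id), function(g) {
    elig <- intersect(g$probeset_id[g$category == want], rownames(x))
    if (!length(elig)) return(NULL)
    data.frame(gene_id = g$gene_id[1],
               probeset_id = elig[which.max(score[elig])],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped)
    warnf("%d gene(s) with no eligible '%s' probe set omitted", dropped, want)
  out <- do.call(rbind, res)
  if (is.null(out)) stopf("no gene has an eligible probe set")
  rownames(out) <- NULL
  out
}

#' Row-wise z-scores
#'
#' Centers and scales every row to mean 0 and (population) standard
#' deviation 1, the convention of row-normalized heat maps. Constant rows
#' are mapped to all zeros with a warning.
#'
#' @param m numeric matrix (features x samples, >= 2 columns).
#' @return matrix of the same dimensions.
#' @export
row_normalize <- function(m) {
  if (ncol(m) < 2L) stopf("need at least 2 samples")
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  const <- s == 0
  if (any(const)) {
    warnf("%d constant row(s) mapped to zeros", sum(const))
    s[const] <- 1
  }
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}

#' Hierarchical clustering of samples on Pearson correlation distance
#'
#' Pairwise sample distance is \code{1 - Pearson correlation} computed over
#' the signature rows; agglomeration uses [stats::hclust()] with the
#' configured linkage. Given a fixed input order the result is
#' deterministic (ties are resolved by hclust's fixed agglomeration order).
#'
#' @param m numeric matrix, signature rows x samples (>= 3 samples).
#' @param linkage "complete" (default), "average" or "single".
#' @return an \code{hclust} object.
#' @export
correlation_dendrogram <- function(m, linkage = c("complete", "average",
                                                  "single")) {
  linkage <- match.arg(linkage)
  if (ncol(m) < 3L) stopf("need at least 3 samples to cluster")
  v <- apply(m, 2L, sd)
  if (any(v == 0))
    stopf("zero-variance sample(s): %s",
          paste(colnames(m)[v == 0], collapse = ", "))
  d <- as.dist(1 - cor(m))
  hclust(d, method = linkage)
}

#' Does a set of samples form a clade?
#'
#' TRUE iff the target samples are all and only the leaves of some subtree
#' of the dendrogram — equivalently, some cut of the tree yields exactly
#' the target set as one cluster.
#'
#' @param hc an \code{hclust} object.
#' @param target_labels character vector of leaf labels (a proper,
#'   non-empty subset of the leaves).
#' @return logical.
#' @export
clean_separation <- function(hc, target_labels) {
  labels <- hc$labels
  if (!length(target_labels) || !all(target_labels %in% labels))
    stopf("target labels must be a non-empty subset of the leaves")
  if (length(unique(target_labels)) == length(labels))
    stopf("target set must not contain every leaf")
  target <- sort(match(unique(target_labels), labels))
  if (length(target) == 1L) return(TRUE)  # a leaf is a clade
  # leaf sets of every internal node, bottom-up over the merge matrix
  leafsets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leafsets[[i]] <- sort(unlist(lapply(kids, function(k)
      if (k < 0) -k else leafsets[[k]])))
    if (identical(leafsets[[i]], target)) return(TRUE)
  }
  FALSE
}

#' Randomization null for signature-based separation
#'
#' Draws \code{n_draws} random probe-set samples of size \code{k} (without
#' replacement) from an eligible pool, clusters the samples with each draw
#' and records how often the target samples separate cleanly (form a
#' clade). The resulting fraction calibrates how special an observed
#' signature's separation is.
#'
#' @param se expression SummarizedExperiment (or plain matrix, rows =
#'   probe sets).
#' @param eligible_pool character vector of probe-set ids to draw from
#'   (e.g. all expressed intronic probe sets).
#' @param k draw size (e.g. the signature size).
#' @param n_draws number of random draws.
#' @param target_labels sample labels tested for clean separation.
#' @param seed integer seed; same seed, same result.
#' @param linkage passed to [correlation_dendrogram()].
#' @return list of class \code{randomization_result}: n_draws, n_clean,
#'   fraction_clean, seed, pool_size, k.
#' @export
randomization_null <- function(se, eligible_pool, k, n_draws, target_labels,
                               seed, linkage = "complete") {
  m <- if (is.matrix(se)) se else exprs_of(se)
  pool <- intersect(eligible_pool, rownames(m))
  if (length(pool) < k)
    stopf("eligible pool (%d) smaller than draw size k = %d", length(pool), k)
  set.seed(as.integer(seed))
  clean <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    draw <- sample(pool, k)
    hc <- correlation_dendrogram(m[draw, , drop = FALSE], linkage = linkage)
    clean[i] <- clean_separation(hc, target_labels)
  }
  res <- list(n_draws = as.integer(n_draws), n_clean = sum(clean),
              fraction_clean = mean(clean), seed = as.integer(seed),
              pool_size = length(pool), k = as.integer(k))
  class(res) <- "randomization_result"
  res
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "Randomization null: %d/%d draws (%.2f%%) of k = %d from a pool of %d separated the targets cleanly (seed %d)\n",
    x$n_clean, x$n_draws, 100 * x$fraction_clean, x$k, x$pool_size, x$seed))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an \code{hclust} object.
#' @param file optional path; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  build <- function(k) {
    if (k < 0) return(hc$labels[-k])
    kids <- hc$merge[k, ]
    h <- hc$height[k]
    branch <- function(j) {
      child_h <- if (j < 0) 0 else hc$height[j]
      sprintf("%s:%g", build(j), h - child_h)
    }
    sprintf("(%s,%s)", branch(kids[1]), branch(kids[2]))
  }
  nwk <- paste0(build(nrow(hc$merge)), ";")
  if (is.null(file)) return(nwk)
  writeLines(nwk, file)
  invisible(nwk)
}
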