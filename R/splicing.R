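# 2^-ddCt relative quantification of qRT-PCR amplicons, genotype ratio
# summaries for exonic vs intronic amplicons, splicing-change
# classification and protein-level prediction from spliced-message
# estimates.

#' Relative quantification by 2^-ddCt
#'
#' For each record: dCt = Ct(target) - Ct(reference gene, same sample);
#' ddCt = dCt - mean dCt over the calibrator group (per gene, amplicon
#' type and experiment); relative quantity = 2^-ddCt. Assumes ideal
#' doubling per cycle.
#'
#' @param records data.frame with columns gene, amplicon_type, sample,
#'   group, experiment, ct.
#' @param reference_gene name of the normalizer gene (present for every
#'   sample).
#' @param calibrator_group group whose mean dCt defines quantity 1.
#' @return the records of the non-reference genes with added columns dct,
#'   ddct, quantity.
#' @export
ddct_quantify <- function(records, reference_gene = "Gapdh",
                          calibrator_group) {
  need <- c("gene", "amplicon_type", "sample", "group", "experiment", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("Ct table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(records$ct))) stopf("non-finite Ct values")
  if (!calibrator_group %in% records$group)
    stopf("calibrator group '%s' not in the data", calibrator_group)

  ref <- records[records$gene == reference_gene, , drop = FALSE]
  tgt <- records[records$gene != reference_gene, , drop = FALSE]
  if (!nrow(ref)) stopf("no records for reference gene '%s'", reference_gene)
  ref_ct <- vapply(split(ref$ct, ref$sample), mean, 0)
  missing_ref <- setdiff(unique(tgt$sample), names(ref_ct))
  if (length(missing_ref))
    stopf("no reference-gene Ct for sample(s): %s",
          paste(missing_ref, collapse = ", "))

  tgt$dct <- tgt$ct - ref_ct[tgt$sample]
  key <- interaction(tgt$gene, tgt$amplicon_type, tgt$experiment, drop = TRUE)
  cal_mean <- vapply(split(seq_len(nrow(tgt)), key), function(i) {
    j <- i[tgt$group[i] == calibrator_group]
    if (!length(j))
      stopf("no calibrator-group record for %s", key[i[1]])
    mean(tgt$dct[j])
  }, 0)
  tgt$ddct <- tgt$dct - cal_mean[as.character(key)]
  tgt$quantity <- 2^(-tgt$ddct)
  rownames(tgt) <- NULL
  tgt
}

#' Per-gene genotype ratio summary (exonic vs intronic amplicons)
#'
#' Within each experiment the ratio is mean quantity in \code{group_a} over
#' mean quantity in \code{group_b}, per gene and amplicon type; across
#' experiments the summary is the median, with dispersion reported as the
#' (unscaled) median absolute deviation. Exonic and intronic amplicons are
#' returned side by side; other amplicon types (exon-intron,
#' intron-spanning) are summarized in the \code{"other"} attribute.
#'
#' @param quantities output of [ddct_quantify()].
#' @param group_a numerator group (e.g. wild-type).
#' @param group_b denominator group.
#' @return data.frame: gene, mrna_ratio, mrna_mad, intronic_ratio,
#'   intronic_mad, n_experiments.
#' @export
genotype_ratio_summary <- function(quantities, group_a, group_b) {
  if (any(quantities$quantity <= 0)) stopf("nonpositive relative quantity")
  per_exp <- do.call(rbind, lapply(
    split(quantities,
          list(quantities$gene, quantities$amplicon_type,
               quantities$experiment), drop = TRUE),
    function(q) {
      qa <- q$quantity[q$group == group_a]
      qb <- q$quantity[q$group == group_b]
      if (!length(qa) || !length(qb)) return(NULL)
      data.frame(gene = q$gene[1], amplicon_type = q$amplicon_type[1],
                 experiment = q$experiment[1], ratio = mean(qa) / mean(qb),
                 stringsAsFactors = FALSE)
    }))
  if (is.null(per_exp)) stopf("no gene has records in both groups")
  summ <- do.call(rbind, lapply(
    split(per_exp, list(per_exp$gene, per_exp$amplicon_type), drop = TRUE),
    function(p) data.frame(gene = p$gene[1], amplicon_type = p$amplicon_type[1],
                           ratio = median(p$ratio),
                           mad = mad(p$ratio, constant = 1),
                           n_experiments = nrow(p), stringsAsFactors = FALSE)))
  main <- summ[summ$amplicon_type %in% c("exonic", "intronic"), , drop = FALSE]
  out <- do.call(rbind, lapply(split(main, main$gene), function(s) {
    ex <- s[s$amplicon_type == "exonic", ]
    intr <- s[s$amplicon_type == "intronic", ]
    if (!nrow(ex) || !nrow(intr)) return(NULL)
    data.frame(gene = s$gene[1],
               mrna_ratio = ex$ratio, mrna_mad = ex$mad,
               intronic_ratio = intr$ratio, intronic_mad = intr$mad,
               n_experiments = min(ex$n_experiments, intr$n_experiments),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stopf("no gene has both exonic and intronic amplicons")
  rownames(out) <- NULL
  attr(out, "other") <- summ[!summ$amplicon_type %in% c("exonic", "intronic"), ,
                             drop = FALSE]
  out
}

#' Classify a gene's splicing-change pattern
#'
#' A ratio is "within" the fold-change band when it lies in
#' \[1/cutoff, cutoff\]. Classes: both within, \code{no_change}; mRNA
#' within but intronic outside, \code{selective_intronic} (unspliced
#' fraction changed while total mRNA did not); both outside,
#' \code{proportional}; mRNA outside with intronic within,
#' \code{mRNA_only}.
#'
#' @param mrna_ratio,intronic_ratio positive linear ratios (vectorized).
#' @param cutoff fold-change band limit (default 1.5).
#' @return character vector of classes.
#' @export
classify_splicing_change <- function(mrna_ratio, intronic_ratio,
                                     cutoff = 1.5) {
  if (any(mrna_ratio <= 0) || any(intronic_ratio <= 0))
    stopf("ratios must be positive")
  within <- function(r) r >= 1 / cutoff & r <= cutoff
  m <- within(mrna_ratio)
  i <- within(intronic_ratio)
  ifelse(m & i, "no_change",
         ifelse(m & !i, "selective_intronic",
                ifelse(!m & !i, "proportional", "mRNA_only")))
}

#' Predict relative protein abundance from spliced-message estimates
#'
#' Only fully spliced message is translated, so the protein ratio between
#' two conditions should track the spliced — not the total — transcript
#' ratio. Reports the naive full-length ratio F = total_A/total_B, the
#' full-length-over-unspliced ratio F/U, and the spliced-message estimate
#' \code{(total_A - c * unspliced_A) / (total_B - c * unspliced_B)}, where
#' the calibration constant \code{c} maps intronic-amplicon units onto
#' total-mRNA units (default 1: both measured on the same relative scale).
#'
#' @param total_a,total_b total-mRNA quantities in conditions A and B.
#' @param unspliced_a,unspliced_b unspliced-transcript quantities.
#' @param calibration calibration constant c (> 0).
#' @param observed_protein optional measured protein ratio A/B (e.g. from
#'   densitometry), carried through for comparison.
#' @return list of class \code{protein_prediction}: full_length_ratio,
#'   full_over_unspliced_ratio, spliced_estimate_ratio, observed_protein.
#' @export
predicted_protein_ratio <- function(total_a, unspliced_a, total_b,
                                    unspliced_b, calibration = 1,
                                    observed_protein = NULL) {
  if (total_a <= 0 || total_b <= 0) stopf("totals must be positive")
  if (unspliced_a < 0 || unspliced_b < 0) stopf("unspliced quantities must be >= 0")
  if (calibration <= 0) stopf("'calibration' must be positive")
  sp_a <- total_a - calibration * unspliced_a
  sp_b <- total_b - calibration * unspliced_b
  if (sp_a <= 0 || sp_b <= 0)
    stopf(paste0("unspliced exceeds total under calibration c = %g ",
                 "(spliced A = %.3g, B = %.3g); lower c or check units"),
          calibration, sp_a, sp_b)
  res <- list(
    full_length_ratio = total_a / total_b,
    full_over_unspliced_ratio = (total_a / unspliced_a) / (total_b / unspliced_b),
    spliced_estimate_ratio = sp_a / sp_b,
    calibration = calibration,
    observed_protein = observed_protein)
  class(res) <- "protein_prediction"
  res
}

#' @export
print.protein_prediction <- function(x, ...) {
  cat(sprintf("F (full-length) = %.3g;  F/U = %.3g;  spliced estimate = %.3g\n",
              x$full_length_ratio, x$full_over_unspliced_ratio,
              x$spliced_estimate_ratio))
  if (!is.null(x$observed_protein))
    cat(sprintf("observed protein ratio = %.3g\n", x$observed_protein))
  invisible(x)
}
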