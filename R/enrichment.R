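# Category tallies of differentially expressed probe sets and the
# intronic-enrichment chi-square test against the array background.

tally_levels <- c("mRNA", "intronic", "repeat", "ambiguous")

#' Tally differentially expressed probe sets by category and direction
#'
#' @param de_records data.frame from [paired_differential_expression()].
#' @param annotation data.frame from [annotate_array()]\code{$annotation}
#'   (columns probeset_id, category).
#' @param background list from [background_fraction()] (attached to the
#'   result for the expected-count model); optional.
#' @param strict error (instead of warn-and-count-as-ambiguous) when a DE
#'   probe set has no annotation.
#' @return list of class \code{category_tally}: \code{counts} (category x
#'   direction matrix), \code{total_de}, \code{expected_intronic} (per
#'   direction, when a background is supplied), \code{background}.
#' @export
tally_categories <- function(de_records, annotation, background = NULL,
                             strict = FALSE) {
  counts <- matrix(0L, length(tally_levels), 2L,
                   dimnames = list(tally_levels, c("up", "down")))
  if (nrow(de_records)) {
    cat <- annotation$category[match(de_records$probeset_id,
                                     annotation$probeset_id)]
    if (anyNA(cat)) {
      missing <- de_records$probeset_id[is.na(cat)]
      if (strict)
        stopf("no annotation for DE probe set(s): %s",
              paste(missing, collapse = ", "))
      warnf("%d DE probe set(s) without annotation counted as ambiguous",
            length(missing))
      cat[is.na(cat)] <- "ambiguous"
    }
    cat[cat == "unmapped"] <- "ambiguous"
    tab <- table(factor(cat, levels = tally_levels),
                 factor(de_records$direction, levels = c("up", "down")))
    counts[] <- as.integer(tab)
  }
  res <- list(counts = counts, total_de = sum(counts),
              background = background)
  if (!is.null(background))
    res$expected_intronic <- c(
      up = expected_intronic_count(res$total_de, background$fraction),
      down = expected_intronic_count(res$total_de, background$fraction))
  class(res) <- "category_tally"
  res
}

#' @export
print.category_tally <- function(x, ...) {
  m <- x$counts
  if (!is.null(x$expected_intronic)) {
    disp <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
    disp["intronic", ] <- sprintf("%d (%d)", m["intronic", ], x$expected_intronic)
    print(as.data.frame(disp))
  } else print(m)
  cat("total DE probe sets:", x$total_de, "\n")
  invisible(x)
}

#' Expected intronic count per direction
#'
#' Under the null that differentially expressed probe sets draw intronic
#' members at the array background rate, with the expectation split evenly
#' between the up and down directions:
#' \code{round(background_fraction * total_de / 2)}, rounding halves away
#' from zero.
#'
#' @param total_de total differentially expressed probe sets (both
#'   directions).
#' @param background_fraction array background intronic fraction (default
#'   0.15).
#' @return integer expected count per direction.
#' @export
expected_intronic_count <- function(total_de, background_fraction = 0.15) {
  if (background_fraction < 0 || background_fraction > 1)
    stopf("'background_fraction' must lie in [0, 1]")
  if (total_de < 0) stopf("'total_de' must be >= 0")
  as.integer(floor(background_fraction * total_de / 2 + 0.5))
}

#' Chi-square test of intronic enrichment over the array background
#'
#' Pearson chi-square with one degree of freedom on the 2x2 table
#' contrasting the tested probe sets (intronic vs not) with the remainder
#' of the array background, two-sided, with Yates continuity correction by
#' default (the corrected statistic is clamped at zero).
#'
#' @param observed_intronic intronic probe sets among those tested.
#' @param n_tested number of probe sets tested (e.g. all differentially
#'   expressed, or the down-regulated ones).
#' @param background_intronic,background_total intronic and total probe-set
#'   counts on the array (the tested sets are a subset of these).
#' @param continuity apply the Yates continuity correction (default TRUE).
#' @return list of class \code{enrichment_result}: statistic, p_value,
#'   observed_fraction, background_fraction, continuity, table.
#' @export
intronic_enrichment_test <- function(observed_intronic, n_tested,
                                     background_intronic, background_total,
                                     continuity = TRUE) {
  if (observed_intronic > n_tested)
    stopf("'observed_intronic' cannot exceed 'n_tested'")
  if (background_intronic <= 0 || background_total <= 0)
    stopf("background counts must be positive")
  if (observed_intronic > background_intronic ||
      n_tested - observed_intronic > background_total - background_intronic)
    stopf("tested set is not a subset of the background counts")
  tab <- matrix(c(observed_intronic, n_tested - observed_intronic,
                  background_intronic - observed_intronic,
                  (background_total - background_intronic) -
                    (n_tested - observed_intronic)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("tested", "rest"),
                                c("intronic", "non_intronic")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(expected) < 1)
    warnf("expected cell count below 1 (min %.3g); chi-square approximation is poor",
          min(expected))
  ct <- suppressWarnings(chisq.test(tab, correct = continuity))
  res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
              observed_fraction = observed_intronic / n_tested,
              background_fraction = background_intronic / background_total,
              continuity = continuity, table = tab)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Intronic enrichment: %.1f%% observed vs %.1f%% background; chi2 = %.3f, p = %.3g%s\n",
    100 * x$observed_fraction, 100 * x$background_fraction, x$statistic,
    x$p_value, if (x$continuity) " (continuity-corrected)" else ""))
  invisible(x)
}
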