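#' Kal's two-proportion z-test
#'
#' Compares a gene's read proportion between two libraries without
#' replicates. With `p1 = x1/N1`, `p2 = x2/N2` and pooled
#' `p0 = (x1 + x2)/(N1 + N2)`, the statistic is
#' `z = (p1 - p2) / sqrt(p0 (1 - p0) (1/N1 + 1/N2))` and the two-sided
#' p-value is `2 (1 - Phi(|z|))`. The squared statistic equals the 2x2
#' Pearson chi-square without continuity correction. Degenerate columns
#' (`x1 = x2 = 0`, or `p0 = 1`) have an undefined z; they are reported with
#' `z = 0`, `p = 1` and the `degenerate` flag set.
#'
#' All arguments are vectorised and recycled.
#'
#' @param x1,x2 read counts in samples 1 and 2.
#' @param N1,N2 library-size denominators.
#' @return data frame `p1`, `p2`, `p0`, `z`, `p_value`, `degenerate`.
#' @export
kal_ztest <- function(x1, N1, x2, N2) {
  stopifnot(all(N1 > 0), all(N2 > 0), all(x1 >= 0), all(x2 >= 0),
            all(x1 <= N1), all(x2 <= N2))
  n <- max(length(x1), length(x2), length(N1), length(N2))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  p1 <- x1 / N1
  p2 <- x2 / N2
  p0 <- (x1 + x2) / (N1 + N2)
  degenerate <- p0 <= 0 | p0 >= 1
  denom <- sqrt(p0 * (1 - p0) * (1 / N1 + 1 / N2))
  z <- ifelse(degenerate, 0, (p1 - p2) / denom)
  p <- 2 * pnorm(-abs(z))
  data.frame(p1 = p1, p2 = p2, p0 = p0, z = z, p_value = p,
             degenerate = degenerate)
}

#' Signed fold change
#'
#' Converts a ratio r to the signed-fold convention used in pairwise
#' comparison tables: r when r >= 1, and -1/r when r < 1, so that the
#' magnitude is always at least 1 and the sign tracks the direction of
#' change.
#'
#' @param r ratio of proportions (sample 1 over sample 2).
#' @return signed fold change.
#' @export
signed_fold <- function(r) {
  ifelse(is.na(r), NA_real_, ifelse(r >= 1, r, -1 / r))
}

#' Pairwise sample comparison
#'
#' Runs [kal_ztest()] per gene between two expression tables that share an
#' annotation, using the coding-read denominators of each table (the same
#' denominators that normalise RPKM). Fold changes are ratios of
#' proportions; genes with a zero count in exactly one sample get an
#' infinite signed fold and are excluded from summary counts. Entries with
#' `p > alpha` carry the insignificance flag, rendered as a trailing `*` by
#' [render_fold()].
#'
#' @param table1,table2 [compute_rpkm()] tables on the same annotation.
#' @param alpha significance level (default 0.05).
#' @param genes optional locus tags to restrict the comparison.
#' @param style `"signed"` reports signed folds (the -1.02 convention);
#'   `"ratio"` reports raw ratios (0.54-style values below 1).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`: raw p-values).
#' @param pseudocount added to both counts before forming ratios (0 keeps
#'   zero-count genes infinite rather than distorting finite folds).
#' @return a `de_result` data frame.
#' @export
compare_samples <- function(table1, table2, alpha = 0.05, genes = NULL,
                            style = c("signed", "ratio"), adjust = "none",
                            pseudocount = 0) {
  style <- match.arg(style)
  stopifnot(identical(table1$locus_tag, table2$locus_tag))
  keep <- if (is.null(genes)) rep(TRUE, nrow(table1))
          else table1$locus_tag %in% genes
  # the test is defined on the ncRNA-removed library: rRNA/tRNA rows are not
  # part of the denominator and cannot be compared against it
  if (!is.null(table1$rna_class))
    keep <- keep & !(table1$rna_class %in% c("rRNA", "tRNA"))
  t1 <- table1[keep, , drop = FALSE]
  t2 <- table2[keep, , drop = FALSE]
  N1 <- attr(table1, "denominator")
  N2 <- attr(table2, "denominator")
  zt <- kal_ztest(t1$count, N1, t2$count, N2)
  zt$p_value <- p.adjust(zt$p_value, method = adjust)
  r <- (t1$count + pseudocount) / N1 / ((t2$count + pseudocount) / N2)
  r[t1$count == 0 & t2$count == 0 & pseudocount == 0] <- NA_real_
  fold <- if (style == "signed") signed_fold(r) else r
  out <- data.frame(locus_tag = t1$locus_tag, annotation = t1$annotation,
                    functional_class = t1$functional_class,
                    x1 = t1$count, x2 = t2$count,
                    p1 = zt$p1, p2 = zt$p2, z = zt$z, p_value = zt$p_value,
                    ratio = r, fold = fold,
                    insignificant = zt$p_value > alpha,
                    degenerate = zt$degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "samples") <- c(attr(table1, "sample"), attr(table2, "sample"))
  attr(out, "n_up") <- sum(is.finite(out$fold) & out$fold > 1 &
                             !out$insignificant)
  attr(out, "n_down") <- sum(is.finite(out$fold) & out$fold < 1 &
                               !out$insignificant)
  attr(out, "n_insignificant") <- sum(out$insignificant)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Render signed folds with the insignificance flag
#'
#' @param results a [compare_samples()] result.
#' @param digits decimal places.
#' @return character vector such as `"2.72"` or `"-1.02*"`.
#' @export
render_fold <- function(results, digits = 2) {
  paste0(formatC(results$fold, format = "f", digits = digits),
         ifelse(results$insignificant, "*", ""))
}

#' Transposase expression summary
#'
#' Per-sample summed transposase RPKM, the number of transposase ORFs above
#' the sample median RPKM, and (when comparisons are supplied) the number of
#' transposase ORFs significantly up-regulated in each comparison.
#'
#' @param tables named list of [compute_rpkm()] tables.
#' @param comparisons optional named list of [compare_samples()] results.
#' @return list with `per_sample` (data frame `sample`, `sum_rpkm`,
#'   `n_above_median`, `n_transposase`) and `per_comparison` (data frame
#'   `comparison`, `n_significant_up`) or `NULL`.
#' @export
transposase_summary <- function(tables, comparisons = NULL) {
  per_sample <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    tr <- tb$functional_class == "transposase"
    data.frame(sample = nm,
               n_transposase = sum(tr),
               sum_rpkm = sum(tb$rpkm[tr]),
               n_above_median = sum(tb$rpkm[tr] > attr(tb, "median_rpkm")),
               stringsAsFactors = FALSE)
  }))
  per_comparison <- NULL
  if (!is.null(comparisons)) {
    per_comparison <- do.call(rbind, lapply(names(comparisons), function(nm) {
      cmp <- comparisons[[nm]]
      tr <- cmp$functional_class == "transposase"
      data.frame(comparison = nm,
                 n_significant_up = sum(tr & is.finite(cmp$fold) &
                                          cmp$fold > 1 & !cmp$insignificant),
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_sample = per_sample, per_comparison = per_comparison)
}
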