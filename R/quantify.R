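#' Count assigned reads per feature
#'
#' Each assigned read (status `unique` or `ambiguous_assigned`) increments
#' exactly one feature: the one containing the read's 5' start (the leftmost
#' aligned base for forward-strand alignments, the rightmost for
#' reverse-strand alignments). Reads starting outside every feature fall
#' into an intergenic bucket. Discarded and unmapped reads are not counted.
#'
#' @param alignments a [map_readset()] result.
#' @param annotation annotation data frame (non-overlapping features).
#' @return data frame `locus_tag`, `count` covering every annotated feature
#'   (zeros included), with attributes `intergenic` (count) and
#'   `total_assigned`.
#' @export
count_reads <- function(alignments, annotation) {
  assigned <- alignments$status %in% c("unique", "ambiguous_assigned")
  a <- alignments[assigned, , drop = FALSE]
  len <- nchar(a$seq)
  five_prime <- ifelse(a$strand_ref == "+", a$pos, a$pos + len - 1L)

  ord <- order(annotation$start)
  starts <- annotation$start[ord]
  ends <- annotation$end[ord]
  fi <- findInterval(five_prime, starts)
  inside <- fi > 0 & five_prime <= ends[pmax(fi, 1L)]
  locus <- rep(NA_character_, length(five_prime))
  locus[inside] <- annotation$locus_tag[ord][fi[inside]]

  tab <- table(factor(locus, levels = annotation$locus_tag))
  out <- data.frame(locus_tag = annotation$locus_tag,
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "intergenic") <- sum(!inside)
  attr(out, "total_assigned") <- nrow(a)
  out
}

#' RPKM expression table
#'
#' RPKM for gene g is `C_g / ((L_g / 1000) * (N / 1e6))` with `C_g` the read
#' count, `L_g` the annotated gene length and `N` the library-size
#' denominator. With `exclude_ncrna = TRUE` (the default) reads assigned to
#' rRNA/tRNA features are removed from `N`, so disparate ribosomal carry-over
#' between libraries does not depress coding RPKM; RPKM values are still
#' reported for the ncRNA features themselves (against the same coding
#' denominator) so tRNAs can be ranked. Reads discarded as too ambiguous were
#' never assigned and appear in no numerator or denominator.
#'
#' @param counts result of [count_reads()].
#' @param annotation annotation data frame.
#' @param sample sample label stored on the table.
#' @param exclude_ncrna remove rRNA/tRNA reads from the denominator.
#' @return an `expression_table` data frame (`locus_tag`, `annotation`,
#'   `rna_class`, `functional_class`, `length`, `count`, `rpkm`) with
#'   attributes `sample`, `total_mapped`, `coding_mapped`, `median_rpkm`
#'   (median over mRNA features).
#' @export
compute_rpkm <- function(counts, annotation, sample = "sample",
                         exclude_ncrna = TRUE) {
  m <- match(annotation$locus_tag, counts$locus_tag)
  stopifnot(!anyNA(m))
  cnt <- counts$count[m]
  len <- annotation$end - annotation$start + 1
  if (any(len <= 0)) stop("annotation contains features of non-positive length")
  is_nc <- annotation$rna_class %in% c("rRNA", "tRNA")
  total <- sum(cnt) + (attr(counts, "intergenic") %||% 0)
  coding <- sum(cnt[!is_nc])
  N <- if (exclude_ncrna) coding else total
  if (N == 0) stop("library-size denominator is zero")
  rpkm <- cnt / ((len / 1000) * (N / 1e6))
  out <- data.frame(locus_tag = annotation$locus_tag,
                    annotation = annotation$annotation,
                    rna_class = annotation$rna_class,
                    functional_class = annotation$functional_class,
                    length = as.integer(len),
                    count = as.integer(cnt),
                    rpkm = rpkm,
                    stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  attr(out, "total_mapped") <- total
  attr(out, "coding_mapped") <- coding
  attr(out, "denominator") <- N
  attr(out, "median_rpkm") <- median(rpkm[annotation$rna_class == "mRNA"])
  class(out) <- c("expression_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dataset statistics by feature category
#'
#' Tabulates, per category, the number of features with at least one
#' assigned read and the number of reads, in the layout of a dataset
#' statistics table: one combined rRNA/tRNA row, one mRNA row, then mRNA
#' subcategories (hypothetical, pseudogenes, transposases, phage proteins,
#' CRISPR-associated). Hypothetical membership is decided by the annotation
#' text containing "hypothetical" (case-insensitive), which also covers
#' "conserved hypothetical protein".
#'
#' @param alignments a [map_readset()] result.
#' @param annotation annotation data frame.
#' @return data frame `category`, `n_orfs_detected`, `n_reads`.
#' @export
dataset_statistics <- function(alignments, annotation) {
  counts <- count_reads(alignments, annotation)
  cnt <- counts$count
  is_nc <- annotation$rna_class %in% c("rRNA", "tRNA")
  groups <- list(
    "rRNA/tRNA" = is_nc,
    "mRNA" = !is_nc,
    "hypothetical" = !is_nc & grepl("hypothetical", annotation$annotation,
                                    ignore.case = TRUE),
    "pseudogenes" = !is_nc & annotation$functional_class == "pseudogene",
    "transposases" = !is_nc & annotation$functional_class == "transposase",
    "phage proteins" = !is_nc & annotation$functional_class == "phage",
    "CRISPRs" = !is_nc & annotation$functional_class == "CRISPR_associated")
  data.frame(
    category = names(groups),
    n_orfs_detected = vapply(groups, function(g) sum(cnt[g] > 0), 0L),
    n_reads = vapply(groups, function(g) sum(cnt[g]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Top expressed features
#'
#' Ranks features by descending RPKM, omitting the requested RNA classes
#' (ribosomal RNA by default; tRNAs stay eligible for ranking). Ties are
#' broken by locus tag order.
#'
#' @param table an [compute_rpkm()] expression table.
#' @param n number of features to report.
#' @param omit RNA classes excluded from the ranking.
#' @return data frame `annotation`, `locus_tag`, `rpkm` of the top `n`.
#' @export
top_expressed <- function(table, n = 100L, omit = "rRNA") {
  keep <- !(table$rna_class %in% omit)
  t2 <- table[keep, , drop = FALSE]
  stopifnot(n <= nrow(t2))
  ord <- order(-t2$rpkm, t2$locus_tag)
  head(t2[ord, c("annotation", "locus_tag", "rpkm")], n)
}

#' Count annotations matching a category pattern
#'
#' Convenience used for top-N table bookkeeping, e.g. counting hypothetical
#' proteins among the 100 most expressed genes of a condition.
#'
#' @param x data frame with an `annotation` column.
#' @param pattern regular expression (default "hypothetical").
#' @return integer count.
#' @export
count_category <- function(x, pattern = "hypothetical") {
  sum(grepl(pattern, x$annotation, ignore.case = TRUE))
}
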