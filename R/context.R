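#' Transposase density in a moving window
#'
#' Counts transposase ORF midpoints in a sliding window across the genome
#' (250 kb by default). With `step = window` the windows tile the genome and
#' the track total equals the transposase ORF count.
#'
#' @param annotation annotation data frame.
#' @param genome_length genome length in nt.
#' @param window window size in nt (default 250000).
#' @param step slide in nt (default: the window size, i.e. tiling).
#' @return a `density_track` data frame: `start`, `end`, `count`.
#' @export
density_track <- function(annotation, genome_length, window = 250000L,
                          step = window) {
  stopifnot(step > 0, window >= 1)
  if (window > genome_length) stop("window exceeds genome length")
  tr <- annotation[annotation$functional_class == "transposase", ,
                   drop = FALSE]
  mid <- (tr$start + tr$end) / 2
  starts <- seq(1L, genome_length - window + 1L, by = step)
  counts <- vapply(starts, function(s)
    sum(mid >= s & mid <= s + window - 1L), 0L)
  out <- data.frame(start = as.integer(starts),
                    end = as.integer(starts + window - 1L),
                    count = counts)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("density_track", "data.frame")
  out
}

#' Write a density track as bedGraph
#'
#' @param track a [density_track()] result.
#' @param path output file.
#' @param name reference name.
#' @export
write_bedgraph <- function(track, path, name = "chr") {
  lines <- sprintf("%s\t%d\t%d\t%d", name, track$start - 1L, track$end,
                   track$count)
  writeLines(c("track type=bedGraph", lines), path)
  invisible(path)
}

.pearson_chisq <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  X2 <- sum((tab - E)^2 / E)
  list(statistic = X2, p_value = pchisq(X2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Deletion-window enrichment of highly expressed transposases
#'
#' Tests whether transposase ORFs with RPKM strictly above the sample median
#' (the dashed-line threshold of the genome-wide RPKM plot) are
#' over-represented inside previously defined deletion windows. Window
#' membership is decided by ORF midpoint containment. The default is a 2x2
#' Pearson chi-square without continuity correction (df = 1), whose
#' statistic equals the squared two-proportion z. A goodness-of-fit
#' alternative compares the observed number of high-RPKM transposases inside
#' windows against the expectation from the windows' genome fraction, and a
#' permutation option replaces the asymptotic p-value with a Monte Carlo one.
#'
#' @param table an [compute_rpkm()] expression table.
#' @param annotation annotation data frame.
#' @param windows data frame of deletion windows (`start`, `end`).
#' @param genome_length genome length (required for `goodness_of_fit`).
#' @param method `"contingency"` (default) or `"goodness_of_fit"`.
#' @param n_permutations if > 0, a permutation p-value from randomly
#'   reassigning the high-RPKM labels.
#' @return an `enrichment_result` list: `table` (2x2 counts), `statistic`,
#'   `df`, `p_value`, `method`, optionally `p_permutation`.
#' @export
deletion_window_enrichment <- function(table, annotation, windows,
                                       genome_length = NULL,
                                       method = c("contingency",
                                                  "goodness_of_fit"),
                                       n_permutations = 0) {
  method <- match.arg(method)
  tr_idx <- which(annotation$functional_class == "transposase")
  if (!length(tr_idx)) stop("no transposase ORFs annotated")
  m <- match(annotation$locus_tag[tr_idx], table$locus_tag)
  stopifnot(!anyNA(m))
  rpkm <- table$rpkm[m]
  high <- rpkm > attr(table, "median_rpkm")
  mid <- (annotation$start[tr_idx] + annotation$end[tr_idx]) / 2
  inside <- vapply(mid, function(x)
    any(x >= windows$start & x <= windows$end), TRUE)

  tab <- table(factor(high, levels = c(TRUE, FALSE)),
               factor(inside, levels = c(TRUE, FALSE)),
               dnn = c("high_rpkm", "in_window"))
  tab <- matrix(as.integer(tab), 2, 2,
                dimnames = list(high_rpkm = c("yes", "no"),
                                in_window = c("yes", "no")))

  if (method == "contingency") {
    res <- .pearson_chisq(tab)
    if (res$degenerate)
      warning("degenerate margins; p-value set to 1")
  } else {
    stopifnot(!is.null(genome_length))
    wfrac <- sum(windows$end - windows$start + 1) / genome_length
    obs <- c(inside = sum(high & inside), outside = sum(high & !inside))
    expd <- sum(high) * c(wfrac, 1 - wfrac)
    if (any(expd == 0) || sum(high) == 0) {
      res <- list(statistic = 0, p_value = 1, degenerate = TRUE)
      warning("degenerate expectation; p-value set to 1")
    } else {
      X2 <- sum((obs - expd)^2 / expd)
      res <- list(statistic = X2,
                  p_value = pchisq(X2, df = 1, lower.tail = FALSE),
                  degenerate = FALSE)
    }
  }
  out <- list(table = tab, statistic = res$statistic, df = 1L,
              p_value = res$p_value, method = method)
  if (n_permutations > 0) {
    obs_in <- sum(high & inside)
    perm <- replicate(n_permutations, {
      h <- sample(high)
      sum(h & inside)
    })
    out$p_permutation <- (sum(abs(perm - mean(perm)) >=
                                abs(obs_in - mean(perm))) + 1) /
      (n_permutations + 1)
  }
  class(out) <- "enrichment_result"
  out
}

#' Intergenic gap between two annotated features
#'
#' Number of nucleotides strictly between two non-overlapping features:
#' `downstream.start - upstream.end - 1`, symmetric in argument order.
#' Adjacent features have gap 0; overlapping features yield a non-positive
#' value with a warning.
#'
#' @param annotation annotation data frame.
#' @param locusA,locusB locus tags.
#' @return integer gap in nt.
#' @export
intergenic_gap <- function(annotation, locusA, locusB) {
  a <- annotation[annotation$locus_tag == locusA, , drop = FALSE]
  b <- annotation[annotation$locus_tag == locusB, , drop = FALSE]
  if (nrow(a) != 1 || nrow(b) != 1) stop("both loci must be annotated once")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  gap <- b$start - a$end - 1L
  if (gap < 0) warning("features overlap; gap reported as non-positive")
  as.integer(gap)
}
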