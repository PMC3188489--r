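#' Primer efficiency from a dilution standard curve
#'
#' Least-squares fit of Ct against log10 template amount over a dilution
#' series; the per-cycle amplification factor is `E = 10^(-1/slope)`. A
#' perfectly doubling assay has slope `-1/log10(2) ~ -3.32` and `E = 2`.
#'
#' @param log10_amount log10 of the template amounts.
#' @param ct observed Ct values (same length, >= 3 points).
#' @return list with `efficiency`, `slope`, `r_squared`.
#' @export
efficiency_from_standard_curve <- function(log10_amount, ct) {
  stopifnot(length(log10_amount) == length(ct), length(ct) >= 3)
  fit <- lm(ct ~ log10_amount)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1)
    stop("standard-curve slope too shallow: assay is not amplifying")
  # noise-free dilution series fit exactly; the perfect-fit warning from
  # summary.lm is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(efficiency = 10^(-1 / slope), slope = slope, r_squared = r2)
}

#' RT-qPCR panel
#'
#' Holds triplicate Ct readings per (target, sample) together with per-target
#' amplification efficiencies and the reference gene used for
#' standardisation (glnA by default).
#'
#' @param ct data frame with columns `target`, `sample`, `replicate`, `ct`.
#' @param efficiencies named numeric vector of per-target efficiencies `E`
#'   (fold amplification per cycle; ideal 2), covering every target
#'   including the reference.
#' @param reference reference gene label (default `"glnA"`).
#' @return a `qpcr_panel` object.
#' @export
qpcr_panel <- function(ct, efficiencies, reference = "glnA") {
  stopifnot(all(c("target", "sample", "replicate", "ct") %in% names(ct)),
            all(ct$ct > 0))
  targets <- unique(ct$target)
  if (!reference %in% targets)
    stop("reference gene '", reference, "' absent from the Ct table")
  missing <- setdiff(targets, names(efficiencies))
  if (length(missing))
    stop("missing efficiencies for: ", paste(missing, collapse = ", "))
  if (any(efficiencies <= 1 | efficiencies > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  reps <- tapply(ct$ct, interaction(ct$target, ct$sample, drop = TRUE),
                 length)
  if (any(reps < 2))
    stop("at least 2 replicates per (target, sample) are required")
  structure(list(ct = ct, efficiencies = efficiencies,
                 reference = reference),
            class = "qpcr_panel")
}

.ct_stats <- function(panel, target, sample) {
  v <- panel$ct$ct[panel$ct$target == target & panel$ct$sample == sample]
  if (!length(v)) stop("no Ct values for ", target, " in ", sample)
  list(mean = mean(v), var = var(v), n = length(v))
}

#' Pfaffl efficiency-corrected relative expression
#'
#' The expression of `target` in `sample` relative to `calibrator`,
#' standardised against the panel's reference gene:
#' `R = E_t^(dCt_t) / E_ref^(dCt_ref)` with
#' `dCt = Ct(calibrator) - Ct(sample)` from triplicate means, so higher
#' expression in the sample gives `R > 1`. With both efficiencies equal to 2
#' this reduces to the `2^-ddCt` method. The standard error is propagated
#' from the triplicate Ct variances by the delta method on `log R`;
#' reference-gene variance is included by default.
#'
#' @param panel a [qpcr_panel()].
#' @param target target gene.
#' @param sample sample of interest.
#' @param calibrator baseline sample.
#' @param include_reference_var include the reference gene's Ct variance in
#'   the propagated error.
#' @return data frame `target`, `sample`, `calibrator`, `ratio`, `se`.
#' @export
pfaffl_ratio <- function(panel, target, sample, calibrator,
                         include_reference_var = TRUE) {
  stopifnot(inherits(panel, "qpcr_panel"))
  Et <- unname(panel$efficiencies[target])
  Er <- unname(panel$efficiencies[panel$reference])
  if (is.na(Et)) stop("unknown target: ", target)
  t_cal <- .ct_stats(panel, target, calibrator)
  t_sam <- .ct_stats(panel, target, sample)
  r_cal <- .ct_stats(panel, panel$reference, calibrator)
  r_sam <- .ct_stats(panel, panel$reference, sample)
  dct_t <- t_cal$mean - t_sam$mean
  dct_r <- r_cal$mean - r_sam$mean
  ratio <- Et^dct_t / Er^dct_r
  var_log <- log(Et)^2 * (t_cal$var / t_cal$n + t_sam$var / t_sam$n)
  if (include_reference_var)
    var_log <- var_log + log(Er)^2 * (r_cal$var / r_cal$n +
                                        r_sam$var / r_sam$n)
  se <- ratio * sqrt(var_log)
  data.frame(target = target, sample = sample, calibrator = calibrator,
             ratio = ratio, se = se, stringsAsFactors = FALSE)
}

#' Panel-wide relative expression report
#'
#' One [pfaffl_ratio()] row per (target, comparison): fold change and
#' triplicate standard error, in the layout of a per-IS-family fold-change
#' figure.
#'
#' @param panel a [qpcr_panel()].
#' @param comparisons data frame with columns `sample`, `calibrator`.
#' @param include_reference_var see [pfaffl_ratio()].
#' @return data frame of ratios for every non-reference target.
#' @export
panel_report <- function(panel, comparisons, include_reference_var = TRUE) {
  stopifnot(all(c("sample", "calibrator") %in% names(comparisons)))
  targets <- setdiff(unique(panel$ct$target), panel$reference)
  rows <- list()
  for (tg in targets)
    for (ci in seq_len(nrow(comparisons)))
      rows[[length(rows) + 1L]] <- pfaffl_ratio(
        panel, tg, comparisons$sample[ci], comparisons$calibrator[ci],
        include_reference_var)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthesize a qPCR panel with known fold changes
#'
#' Inverse construction for validation: Ct values are generated from the
#' amplification model `Ct(sample) = Ct(calibrator) - log(fold)/log(E)` for
#' each target (the reference gene shifts identically in both samples) with
#' Gaussian cycle noise, so the Pfaffl analysis should recover the requested
#' folds.
#'
#' @param folds named numeric vector of true fold changes per target.
#' @param efficiency amplification efficiency used for every primer pair
#'   (scalar or named vector including the reference).
#' @param sample,calibrator sample labels.
#' @param reference reference gene label.
#' @param base_ct calibrator-side mean Ct.
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param n_replicates replicates per (target, sample).
#' @param seed RNG seed.
#' @return a [qpcr_panel()].
#' @export
simulate_qpcr_panel <- function(folds, efficiency = 2, sample = "5dN2",
                                calibrator = "3dNH4", reference = "glnA",
                                base_ct = 22, noise_sd = 0.1,
                                n_replicates = 3, seed = 1) {
  set.seed(seed)
  targets <- c(names(folds), reference)
  eff <- if (length(efficiency) == 1)
    setNames(rep(efficiency, length(targets)), targets) else efficiency
  rows <- list()
  for (tg in targets) {
    fold <- if (tg == reference) 1 else folds[[tg]]
    ct_cal <- base_ct
    ct_sam <- base_ct - log(fold) / log(eff[[tg]])
    for (rep_i in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, sample = calibrator, replicate = rep_i,
        ct = ct_cal + rnorm(1, 0, noise_sd), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, sample = sample, replicate = rep_i,
        ct = ct_sam + rnorm(1, 0, noise_sd), stringsAsFactors = FALSE)
    }
  }
  qpcr_panel(do.call(rbind, rows), eff, reference)
}
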