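#' Fit a qPCR absolute-quantification standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a dilution series
#' (canonically a 10-fold series spanning 1e2 to 1e-3 ng/reaction):
#' `Ct = slope * log10(q) + intercept`. A valid qPCR curve has negative
#' slope (about -3.32 at 100% efficiency).
#'
#' @param log10_quantity Numeric vector, log10 of the known quantities.
#' @param ct Numeric vector of observed Ct values.
#' @return A list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (range of fitted log10 quantities).
#' @export
fit_standard_curve <- function(log10_quantity, ct) {
  if (length(log10_quantity) != length(ct)) stop("inputs must have equal length")
  if (length(unique(log10_quantity)) < 3L) {
    stop("need at least 3 points with distinct quantities")
  }
  fit <- lm(ct ~ log10_quantity)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    range = range(log10_quantity)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: Ct = %.4f * log10(q) + %.4f (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  fitted over log10(q) in [%g, %g]\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Interpolate quantity from Ct on a standard curve
#'
#' Inverts the fitted line: `q = 10^((ct - intercept) / slope)`. Values
#' whose Ct falls outside the fitted dilution range are still returned but
#' flagged as extrapolated.
#'
#' @param ct Numeric vector of Ct values.
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of quantities (same units as the standards),
#'   with logical attribute `extrapolated`.
#' @export
interpolate_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("invalid curve: slope is zero")
  logq <- (ct - curve$intercept) / curve$slope
  q <- 10^logq
  # tolerance keeps boundary standards from flagging through rounding alone
  tol <- 1e-8 * max(1, abs(curve$range))
  attr(q, "extrapolated") <- logq < curve$range[1] - tol | logq > curve$range[2] + tol
  q
}

#' Relative enrichment of a recovered pool or aptamer
#'
#' Ratio of tissue-normalized recovered quantity (ng aptamer per mg
#' tissue) between an enriched sample and the initial (T0) pool. The same
#' ratio with input-cDNA units (ng detected / ng input) expresses relative
#' binding; the arithmetic is identical.
#'
#' @param sample_ng_per_mg Normalized quantity for the enriched sample.
#' @param t0_ng_per_mg Normalized quantity for the initial pool (> 0).
#' @return Fold enrichment (numeric).
#' @export
relative_enrichment <- function(sample_ng_per_mg, t0_ng_per_mg) {
  if (any(t0_ng_per_mg <= 0)) stop("T0 quantity must be > 0")
  sample_ng_per_mg / t0_ng_per_mg
}

#' Fold change by the delta-delta-Ct method
#'
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,cal - Ct_ref,cal))`
#' with PCR efficiency fixed at 2. For the calibrator sample itself the
#' exponent is zero and the fold change is exactly 1.
#'
#' @param ct_target_sample Target-gene Ct in the sample.
#' @param ct_ref_sample Reference-gene Ct in the sample.
#' @param ct_target_cal Target-gene Ct in the calibrator.
#' @param ct_ref_cal Reference-gene Ct in the calibrator.
#' @return Fold change (numeric).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_cal, ct_ref_cal) {
  stopifnot(all(is.finite(c(ct_target_sample, ct_ref_sample,
                            ct_target_cal, ct_ref_cal))))
  ddct <- (ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}
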