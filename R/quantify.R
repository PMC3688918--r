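#' Fit a linear external calibration curve
#'
#' Ordinary least squares of MRM peak area on standard concentration,
#' unweighted, as used for external calibration of targeted analytes. The
#' linear range is the span of the standard series.
#'
#' @param concentration standard concentrations (nM), at least 3 distinct.
#' @param area corresponding peak areas.
#' @param analyte analyte name (optional, carried in the result).
#' @return A `calibration_curve` with `slope`, `intercept`, `r_squared`,
#'   `linear_range` (nM), `points` and `analyte`.
#' @export
fit_calibration <- function(concentration, area, analyte = NA_character_) {
  if (length(unique(concentration)) < 3L)
    stop("need at least 3 distinct standard concentrations")
  if (length(concentration) != length(area)) stop("length mismatch")
  fit <- stats::lm(area ~ concentration)
  tss <- sum((area - mean(area))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  r2 <- min(max(r2, 0), 1)
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 linear_range = range(concentration),
                 points = data.frame(concentration = concentration,
                                     area = area)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration", if (!is.na(x$analyte)) paste0(" [", x$analyte, "]"),
      ": area = ", signif(x$slope, 5), " * conc + ",
      signif(x$intercept, 5), " (R2 = ", round(x$r_squared, 4),
      "), linear range ", x$linear_range[1], "-", x$linear_range[2],
      " nM\n", sep = "")
  invisible(x)
}

#' Quantify an analyte from a calibration curve
#'
#' Inverts the calibration line: `conc = dilution * (area - intercept) /
#' slope`, flagging results outside the calibrated linear range.
#'
#' @param curve a `calibration_curve` from [fit_calibration()].
#' @param area measured peak area(s).
#' @param dilution dilution factor applied to the extract (default 1).
#' @return data.frame with `concentration_nM` and `in_range`.
#' @export
quantify <- function(curve, area, dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero calibration slope")
  conc <- dilution * (area - curve$intercept) / curve$slope
  tol <- 1e-8 * pmax(1, abs(curve$linear_range))  # round-off guard
  data.frame(concentration_nM = conc,
             in_range = conc >= curve$linear_range[1] - tol[1] &
               conc <= curve$linear_range[2] + tol[2])
}

#' Confirm analyte identity from MRM transition evidence
#'
#' Applies the three targeted-MS identity criteria: (i) the quantification
#' and confirmation transitions co-occur in time, (ii) the observed
#' confirmation/quantification abundance ratio lies within +/- 25% of the
#' ratio in a standard of similar concentration, and (iii) both
#' transitions have signal-to-noise ratio strictly above 9. All three
#' must hold for a confirmed identity.
#'
#' @param rt_quant,rt_confirm retention times (min) of the two transitions.
#' @param area_quant,area_confirm peak areas of the two transitions.
#' @param snr_quant,snr_confirm signal-to-noise ratios (inputs; SNR
#'   estimation from raw traces is upstream of this function).
#' @param standard_ratio confirmation/quantification area ratio observed
#'   in a comparable standard; when missing (NA) criterion (ii) is
#'   indeterminate and the identity is not confirmed.
#' @param rt_tolerance co-occurrence tolerance in minutes (default 0.05).
#' @return A `confirmation_result` with logicals `co_occurrence`,
#'   `ratio_within_25pct`, `snr_above_9`, `confirmed` (their conjunction)
#'   and a `reason` when unconfirmed.
#' @export
confirm_identity <- function(rt_quant, rt_confirm, area_quant, area_confirm,
                             snr_quant, snr_confirm, standard_ratio,
                             rt_tolerance = 0.05) {
  stopifnot(area_quant >= 0, area_confirm >= 0)
  co <- abs(rt_quant - rt_confirm) <= rt_tolerance
  snr_ok <- snr_quant > 9 && snr_confirm > 9
  if (is.na(standard_ratio)) {
    ratio_ok <- NA
  } else {
    obs_ratio <- area_confirm / area_quant
    ratio_ok <- obs_ratio >= 0.75 * standard_ratio &&
      obs_ratio <= 1.25 * standard_ratio
  }
  confirmed <- isTRUE(co) && isTRUE(ratio_ok) && isTRUE(snr_ok)
  reason <- NULL
  if (!confirmed) {
    why <- c(if (!isTRUE(co)) "transitions do not co-occur",
             if (is.na(ratio_ok)) "no standard ratio available"
             else if (!ratio_ok) "transition ratio outside +/-25% of standard",
             if (!snr_ok) "SNR not above 9 for both transitions")
    reason <- paste(why, collapse = "; ")
  }
  structure(list(co_occurrence = co, ratio_within_25pct = ratio_ok,
                 snr_above_9 = snr_ok, confirmed = confirmed,
                 reason = reason),
            class = "confirmation_result")
}

#' Convert extract concentration to tissue concentration
#'
#' Tissue extracts homogenized at a fixed tissue density (mg frozen tissue
#' per mL buffer) let extract concentrations be expressed per mg of
#' tissue: `nmol/mg = (nmol/mL) / density`.
#'
#' @param conc extract concentration; units per `units`.
#' @param tissue_density_mg_ml mg tissue per mL extract (default 33.3).
#' @param units `"nmol/mL"` (default) or `"nM"` (converted via
#'   1 nM = 1e-3 nmol/mL).
#' @return Concentration in nmol per mg tissue.
#' @export
tissue_concentration <- function(conc, tissue_density_mg_ml = 33.3,
                                 units = c("nmol/mL", "nM")) {
  units <- match.arg(units)
  if (tissue_density_mg_ml <= 0) stop("tissue density must be positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (units == "nM") conc <- conc / 1000
  conc / tissue_density_mg_ml
}
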