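#' Wound-healing (scratch closure) rate
#'
#' Fractional closure of a scratch gap:
#' (mean initial distance - mean distance at time T) / mean initial
#' distance. A negative value (gap widened) is returned with a warning.
#'
#' @param initial Mean initial intercellular distance (> 0, any length
#'   unit).
#' @param at_time Mean intercellular distance at time T, same unit.
#' @return The healing rate as a fraction.
#' @export
wound_healing_rate <- function(initial, at_time) {
  stopifnot(is.numeric(initial), is.numeric(at_time))
  if (any(initial <= 0)) stop("initial distance must be > 0", call. = FALSE)
  rate <- (initial - at_time) / initial
  if (any(rate < 0)) warning("negative healing rate: gap widened")
  rate
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#'        (Ct_target,control - Ct_ref,control); returns 2^-ddCt, the fold
#' change of the target gene in the treated condition relative to control,
#' normalized to a housekeeping reference (e.g. GAPDH).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   qPCR cycle-threshold values.
#' @return Fold change (2^-ddCt).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Malondialdehyde (MDA) content from plate readings
#'
#' Colorimetric kit formula:
#' (sample OD - control OD) / (standard OD - blank OD) x 10 nmol/mL
#' divided by the protein concentration (mg/mL), giving nmol per mg
#' protein.
#'
#' @param sample_od,control_od,standard_od,blank_od Optical densities.
#' @param protein Protein concentration in mg/mL (> 0).
#' @param standard_conc Standard concentration in nmol/mL (kit default 10).
#' @return MDA content in nmol per mg protein.
#' @export
mda_content <- function(sample_od, control_od, standard_od, blank_od,
                        protein, standard_conc = 10) {
  if (any(standard_od == blank_od)) {
    stop("standard OD equals blank OD; calibration is degenerate",
         call. = FALSE)
  }
  if (any(protein <= 0)) stop("protein concentration must be > 0",
                              call. = FALSE)
  (sample_od - control_od) / (standard_od - blank_od) * standard_conc /
    protein
}

#' Catalase (CAT) activity from an absorbance kinetic
#'
#' Kit formula: delta A (absorbance change per minute at 405 nm) x 235.65,
#' divided by the protein concentration (mg/mL). The kit's reaction-volume
#' and time divisors (0.1 mL, 60 s) are treated as unit bookkeeping folded
#' into the 235.65 constant's definition; set `literal_divisors = TRUE` to
#' additionally divide by 0.1 and 60 (the other reading of the composite
#' formula).
#'
#' @param delta_a Absorbance change per minute.
#' @param protein Protein concentration in mg/mL (> 0).
#' @param literal_divisors Apply /0.1/60 numerically (default FALSE).
#' @return CAT activity in units per mg protein.
#' @export
cat_activity <- function(delta_a, protein, literal_divisors = FALSE) {
  if (any(protein <= 0)) stop("protein concentration must be > 0",
                              call. = FALSE)
  act <- delta_a * 235.65 / protein
  if (literal_divisors) act <- act / 0.1 / 60
  act
}

#' Fit an ELISA-style standard curve
#'
#' Linear: ordinary least squares response ~ concentration. Four-parameter
#' logistic (4PL): response = d + (a - d) / (1 + (conc / c)^b), fitted by
#' Levenberg-Marquardt nonlinear least squares. The fitted curve must be
#' monotone over the calibration range.
#'
#' @param concentration,response Calibration points (>= 2 for linear,
#'   >= 4 for 4PL).
#' @param kind `"linear"` (default) or `"4pl"`.
#' @return A `standard_curve` object with the fitted parameters and the
#'   calibration ranges.
#' @export
fit_standard_curve <- function(concentration, response,
                               kind = c("linear", "4pl")) {
  kind <- match.arg(kind)
  stopifnot(length(concentration) == length(response))
  o <- order(concentration)
  concentration <- concentration[o]
  response <- response[o]
  dr <- diff(response)
  if (!(all(dr >= 0) || all(dr <= 0))) {
    stop("calibration responses are not monotone in concentration",
         call. = FALSE)
  }
  if (kind == "linear") {
    if (length(concentration) < 2) stop(">= 2 points needed", call. = FALSE)
    fit <- stats::lm(response ~ concentration)
    coefs <- stats::coef(fit)
    flat_tol <- .Machine$double.eps^0.5 * max(1, diff(range(response)))
    if (abs(coefs[2]) < flat_tol) stop("flat calibration line", call. = FALSE)
    params <- c(intercept = unname(coefs[1]), slope = unname(coefs[2]))
    fitted <- unname(stats::fitted(fit))
  } else {
    if (length(concentration) < 4) stop(">= 4 points needed for 4PL",
                                        call. = FALSE)
    if (any(concentration <= 0)) {
      stop("4PL needs strictly positive concentrations", call. = FALSE)
    }
    a0 <- response[1]; d0 <- response[length(response)]
    c0 <- stats::median(concentration)
    start <- list(a = a0, b = if (d0 >= a0) 1 else -1, c = c0, d = d0)
    fit <- minpack.lm::nlsLM(
      response ~ d + (a - d) / (1 + (concentration / c)^b),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    params <- stats::coef(fit)
    fitted <- unname(stats::fitted(fit))
  }
  diffs <- diff(fitted)
  if (!(all(diffs >= -1e-9) || all(diffs <= 1e-9))) {
    stop("fitted calibration curve is not monotone over the range",
         call. = FALSE)
  }
  structure(list(kind = kind, params = params,
                 conc_range = range(concentration),
                 response_range = range(fitted)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> ", x$kind, ": ",
      paste(names(x$params), signif(x$params, 6), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Interpolate concentrations from responses on a standard curve
#'
#' Closed-form inversion of the fitted curve. Responses outside the
#' calibrated response range are still inverted but flagged as
#' extrapolated (warning + `extrapolated` attribute).
#'
#' @param curve A `standard_curve`.
#' @param response Numeric vector of measured responses.
#' @return Concentrations, with attribute `extrapolated` (logical vector).
#' @export
interpolate_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "standard_curve"))
  p <- curve$params
  if (curve$kind == "linear") {
    conc <- (response - p["intercept"]) / p["slope"]
  } else {
    ratio <- (p["a"] - p["d"]) / (response - p["d"]) - 1
    conc <- p["c"] * ratio^(1 / p["b"])
  }
  conc <- unname(conc)
  lo <- min(curve$response_range); hi <- max(curve$response_range)
  tol <- 1e-8 * max(1, hi - lo)   # boundary responses are in range
  extra <- response < lo - tol | response > hi + tol
  if (any(extra)) {
    warning(sum(extra), " response(s) outside the calibration range; ",
            "extrapolated")
  }
  attr(conc, "extrapolated") <- extra
  conc
}
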