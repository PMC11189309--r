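# Modification stoichiometry (occupancy) and inhibitor dose-response.

#' Citrullination occupancy from matched modified/unmodified intensities
#'
#' Occupancy = modified / (modified + unmodified), the fraction of protein
#' copies carrying the modification at that arginine, computed from a
#' citrullinated peptide and its unmodified counterpart. When the unmodified
#' counterpart is missing but the modified form is observed, occupancy is
#' reported as 1 and flagged as a boundary value; when both are missing it is
#' undefined (NA), not zero.
#'
#' @param modified,unmodified intensity vectors (NA = missing, values >= 0).
#' @return data.frame with `occupancy` (0-1 or NA) and `boundary` (logical).
#' @export
occupancy <- function(modified, unmodified) {
  stopifnot(length(modified) == length(unmodified))
  if (any(c(modified, unmodified) < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  both_missing <- is.na(modified) & is.na(unmodified)
  boundary <- !is.na(modified) & is.na(unmodified)
  mod <- ifelse(is.na(modified), 0, modified)
  unm <- ifelse(is.na(unmodified), 0, unmodified)
  occ <- ifelse(both_missing, NA_real_, mod / (mod + unm))
  occ[!both_missing & (mod + unm) == 0] <- NA_real_
  data.frame(occupancy = occ, boundary = boundary)
}

.check_series <- function(concentration, response) {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response))
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(response < 0)) stop("responses must be >= 0")
}

#' Model-free half-inhibition concentration
#'
#' Finds the concentration at which the response crosses 50% of the control
#' (0 concentration) response, by log-linear interpolation between the two
#' bracketing concentrations. Errors if the series never reaches
#' half-inhibition.
#'
#' @param concentration increasing concentrations (uM), first entry 0 =
#'   control.
#' @param response responses relative to control (control ~ 1).
#' @return interpolated concentration (uM).
#' @export
half_inhibition <- function(concentration, response) {
  .check_series(concentration, response)
  ctrl <- response[concentration == 0]
  if (length(ctrl) == 0L) ctrl <- response[1]
  half <- 0.5 * mean(ctrl)
  below <- which(response < half)
  if (length(below) == 0L)
    stop("series never reaches half-inhibition (no response below 50% of control)")
  j <- below[1]
  if (j == 1L) return(concentration[1])
  i <- j - 1L
  c_lo <- concentration[i]; c_hi <- concentration[j]
  r_lo <- response[i]; r_hi <- response[j]
  frac <- (half - r_lo) / (r_hi - r_lo)
  if (c_lo <= 0) {
    # control bracket: log interpolation undefined at 0, fall back to linear
    c_lo + frac * (c_hi - c_lo)
  } else {
    exp(log(c_lo) + frac * (log(c_hi) - log(c_lo)))
  }
}

#' Fit a four-parameter log-logistic (4PL) inhibition curve
#'
#' response = bottom + (top - bottom) / (1 + (c / IC50)^slope), with `top`
#' fixed at the control (0 uM) response and `bottom` constrained >= 0.
#' Fitting uses bounded Levenberg-Marquardt least squares. On
#' non-convergence (e.g. a flat series) the fit is flagged and the
#' model-free interpolated value is reported as fallback where available.
#'
#' @param concentration increasing concentrations (uM) including 0 = control.
#' @param response responses relative to control.
#' @return list: `ic50`, `hill_slope`, `top`, `bottom`, `converged`,
#'   `ci50_interpolated`.
#' @export
fit_ic50 <- function(concentration, response) {
  .check_series(concentration, response)
  if (length(concentration) < 4L)
    stop("need at least 4 concentration points including control")
  top <- mean(response[concentration == 0])
  if (!length(top) || is.na(top)) top <- response[1]
  interp <- tryCatch(half_inhibition(concentration, response),
                     error = function(e) NA_real_)
  pos <- concentration[concentration > 0]
  start_ic50 <- if (is.finite(interp) && interp > 0) interp
                else exp(mean(log(pos)))
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (concentration / ic50)^slope),
      data = data.frame(concentration = concentration, response = response),
      start = list(bottom = 0, ic50 = start_ic50, slope = 1),
      lower = c(bottom = 0, ic50 = 1e-9, slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    est <- stats::coef(f)
    # a fit that pinned IC50 at a bound or cannot bend is not informative
    if (!is.finite(est[["ic50"]]) || est[["ic50"]] <= 1e-8) stop("degenerate")
    if (stats::sd(response) < 1e-8) stop("flat series")
    est
  }, error = function(e) NULL)
  if (is.null(fit)) {
    list(ic50 = NA_real_, hill_slope = NA_real_, top = top, bottom = NA_real_,
         converged = FALSE, ci50_interpolated = interp)
  } else {
    list(ic50 = unname(fit[["ic50"]]), hill_slope = unname(fit[["slope"]]),
         top = top, bottom = unname(fit[["bottom"]]),
         converged = TRUE, ci50_interpolated = interp)
  }
}

#' Evaluate the 4PL inhibition model
#'
#' @param concentration concentrations (uM).
#' @param ic50,slope,top,bottom curve parameters.
#' @return response values.
#' @export
four_pl <- function(concentration, ic50, slope = 1, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (concentration / ic50)^slope)
}
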