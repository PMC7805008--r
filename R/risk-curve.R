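#' Exposure-response relative-risk curves
#'
#' A risk curve maps exposure to relative risk for one risk-cause pair.
#' Continuous curves (ambient PM2.5, ozone) are piecewise-linear in exposure
#' with RR = 1 at and below the theoretical minimum-risk exposure level
#' (TMREL) and constant (plateau) extrapolation beyond the last knot.
#' Categorical curves (household solid-fuel use) carry a single RR for the
#' exposed category. Curves are inputs to the pipeline — fitting them is out
#' of scope — and are typically read from `risk_curves.csv` with
#' [read_risk_curves()].
#'
#' @param exposure strictly increasing knot exposures (curve units).
#' @param rr relative risk at each knot (all >= 1).
#' @param tmrel exposure at/below which RR is exactly 1; must not exceed the
#'   first knot.
#' @param risk,cause optional labels attached for bookkeeping.
#' @return Object of class `c("risk_curve_continuous", "risk_curve")` or
#'   `c("risk_curve_categorical", "risk_curve")`.
#' @export
risk_curve_continuous <- function(exposure, rr, tmrel, risk = NA_character_,
                                  cause = NA_character_) {
  if (length(exposure) != length(rr) || length(exposure) < 1L) {
    stop_validation("knot exposures and RRs must have equal positive length")
  }
  if (any(diff(exposure) <= 0)) stop_validation("knot exposures must be strictly increasing")
  if (any(rr < 1)) stop_domain("relative risks below 1 are out of scope")
  if (tmrel > exposure[1L]) stop_validation("tmrel must not exceed the first knot")
  # anchor the curve at (tmrel, 1) so RR(tmrel) = 1 exactly
  if (tmrel < exposure[1L]) {
    exposure <- c(tmrel, exposure)
    rr <- c(1, rr)
  } else {
    rr[1L] <- 1
  }
  structure(
    list(exposure = as.numeric(exposure), rr = as.numeric(rr),
         tmrel = as.numeric(tmrel), risk = risk, cause = cause),
    class = c("risk_curve_continuous", "risk_curve")
  )
}

#' @rdname risk_curve_continuous
#' @param rr_exposed relative risk in the exposed category (>= 1).
#' @export
risk_curve_categorical <- function(rr_exposed, risk = NA_character_,
                                   cause = NA_character_) {
  if (!is_scalar_number(rr_exposed) || rr_exposed < 1) {
    stop_domain("rr_exposed must be a number >= 1")
  }
  structure(
    list(rr_exposed = rr_exposed, risk = risk, cause = cause),
    class = c("risk_curve_categorical", "risk_curve")
  )
}

#' Relative risk at a given exposure
#'
#' Evaluates a continuous risk curve: RR = 1 for exposure at or below the
#' TMREL, linear interpolation between knots, plateau beyond the last knot.
#'
#' @param curve a continuous risk curve.
#' @param exposure exposure value(s), curve units, >= 0.
#' @return Relative risk(s), dimensionless, >= 1.
#' @export
relative_risk <- function(curve, exposure) {
  if (!inherits(curve, "risk_curve_continuous")) {
    stop_type("relative_risk() requires a continuous risk curve")
  }
  if (any(exposure < 0)) stop_domain("exposure must be non-negative")
  out <- stats::approx(curve$exposure, curve$rr, xout = exposure,
                       rule = 2, ties = "ordered")$y
  out[exposure <= curve$tmrel] <- 1
  out
}
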