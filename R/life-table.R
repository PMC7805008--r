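#' Life table with single-year survivorship
#'
#' Survivorship l(x) — the expected number of a birth cohort (radix
#' `l(0) = 100000`) alive at exact age x — at single years of age, carried
#' alongside the abridged anchors at age-group starts it was interpolated
#' from. Conditional survival S(a, a+t) = l(a+t)/l(a) is the quantity the
#' economic model consumes.
#'
#' @param l numeric vector of survivorship at ages `0:(length(l)-1)`.
#' @param grid an [age_grid()]; abridged anchors are taken at its starts.
#' @return Object of class `life_table`: list with `l` (single-year),
#'   `ages`, `abridged` (at grid starts) and `grid`.
#' @export
life_table <- function(l, grid = age_grid()) {
  if (!is.numeric(l) || length(l) < 2L) stop_validation("l must be a numeric vector")
  if (l[1L] <= 0) stop_validation("l(0) must be positive")
  if (any(l < 0)) stop_validation("survivorship must be non-negative")
  if (any(diff(l) > 1e-9 * l[1L])) {
    stop_validation("survivorship must be non-increasing in age")
  }
  ages <- seq_along(l) - 1L
  structure(
    list(l = as.numeric(l), ages = ages,
         abridged = as.numeric(l[pmin(grid$starts, max(ages)) + 1L]),
         grid = grid),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ages 0-", max(x$ages), ", l(0)=", x$l[1L],
      ", l(65)/l(0)=", signif(survival_probability(x, 0, 65), 4), "\n", sep = "")
  invisible(x)
}

#' Conditional survival probability from a life table
#'
#' S(a, a+t) = l(a+t) / l(a): the probability that a person alive at exact
#' age `a` survives `t` further years. Ages beyond the table's last entry
#' are treated as having survivorship equal to the final value.
#'
#' @param lt a [life_table()].
#' @param a current age in years (>= 0).
#' @param t years ahead (>= 0). `a` and `t` may be vectors (recycled).
#' @return Probability in \[0, 1\].
#' @export
survival_probability <- function(lt, a, t) {
  if (any(a < 0) || any(t < 0)) stop_domain("ages and horizons must be non-negative")
  amax <- max(lt$ages)
  la <- lt$l[pmin(floor(a), amax) + 1L]
  if (any(la == 0)) stop_domain("survivorship at current age is zero")
  lat <- lt$l[pmin(floor(a + t), amax) + 1L]
  pmin(pmax(lat / la, 0), 1)
}

#' Generate a seeded synthetic life table
#'
#' Draws a Gompertz-Makeham-style hazard (seeded jitter on its shape) and
#' rescales the cumulative hazard so that survival to 65 matches
#' `target_l65_over_l0` exactly at the abridged anchors; single-year values
#' are linear interpolations of the abridged anchors, so the realised
#' l(65)/l(0) equals the target by construction (65 is an anchor).
#'
#' @param target_l65_over_l0 desired l(65)/l(0), in (0, 1).
#' @param seed integer seed for the shape jitter.
#' @param grid an [age_grid()].
#' @param max_age last single year of age tabulated (default 100).
#' @return A [life_table()].
#' @export
generate_life_table <- function(target_l65_over_l0, seed,
                                grid = age_grid(), max_age = 100L) {
  if (!is_scalar_number(target_l65_over_l0) ||
      target_l65_over_l0 <= 0 || target_l65_over_l0 >= 1) {
    stop_domain("target l(65)/l(0) must lie strictly inside (0, 1)")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  # hazard shape: infant spike + background + Gompertz senescence; the
  # senescent term dominates adult mortality so survivorship has the usual
  # rectangular shape rather than a heavy childhood tail
  b <- stats::runif(1L, 0.085, 0.105)
  infant <- stats::runif(1L, 0.02, 0.05)
  background <- stats::runif(1L, 0.5, 1.5)
  x <- 0:max_age
  h0 <- infant * exp(-1.5 * x) + background * 1e-3 + 4e-5 * exp(b * x)
  H0 <- cumsum(c(0, h0[-length(h0)]))   # cumulative hazard to exact age x
  k <- -log(target_l65_over_l0) / H0[66L]   # rescale so l(65) hits target
  l_model <- 1e5 * exp(-k * H0)
  anchors <- pmin(grid$starts, max_age)
  anchors <- unique(c(anchors, max_age))
  l_single <- stats::approx(anchors, l_model[anchors + 1L], xout = x)$y
  life_table(l_single, grid)
}
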