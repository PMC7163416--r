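#' LDL-c category levels
#'
#' The six ordinal LDL-c management states: on target (LDL-c strictly below
#' the guideline target) or off target by a distance band in mmol/L above the
#' target: `[0, 0.5)`, `[0.5, 1.0)`, `[1.0, 1.5)`, `[1.5, 2.0)`, `[2.0, Inf)`.
#'
#' @return Character vector of the six level names, in ordinal order.
#' @export
ldl_state_levels <- function() {
  c("ON_TARGET", "OFF_LT_0_5", "OFF_0_5_0_9", "OFF_1_0_1_4",
    "OFF_1_5_1_9", "OFF_GE_2_0")
}

#' Categorize LDL-c against the treatment target
#'
#' A measurement is on target when LDL-c is strictly below `target`
#' (guideline default 2.5 mmol/L). Off-target measurements are binned by the
#' distance `ldl - target` into half-open 0.5 mmol/L bands, the top band
#' open-ended at 2.0 mmol/L above target.
#'
#' @param ldl Numeric vector of LDL-c values (mmol/L), non-negative.
#' @param target LDL-c target in mmol/L (default 2.5).
#' @return Ordered factor over [ldl_state_levels()]. `NA` propagates.
#' @examples
#' ldl_state(c(2.4, 2.5, 4.6))
#' @export
ldl_state <- function(ldl, target = 2.5) {
  stopifnot(is.numeric(ldl), length(target) == 1L, target > 0)
  if (any(ldl < 0, na.rm = TRUE)) {
    stop("ldl_state(): negative LDL-c value supplied", call. = FALSE)
  }
  d <- ldl - target
  idx <- ifelse(d < 0, 1L, pmin(floor(d / 0.5), 4) + 2L)
  factor(ldl_state_levels()[idx], levels = ldl_state_levels(), ordered = TRUE)
}

#' Representative LDL-c value for each state
#'
#' Midpoint of each state's mmol/L bin (top bin capped at `cap`); used by the
#' synthetic generator and for round-trip checks.
#'
#' @param state Factor or character vector of state labels.
#' @param target LDL-c target (mmol/L).
#' @param cap Upper LDL-c bound for the open top bin (mmol/L).
#' @return Numeric vector of representative LDL-c values.
#' @export
ldl_state_midpoint <- function(state, target = 2.5, cap = 8.0) {
  lo <- c(0.8, target, target + 0.5, target + 1.0, target + 1.5, target + 2.0)
  hi <- c(target, target + 0.5, target + 1.0, target + 1.5, target + 2.0, cap)
  i <- match(as.character(state), ldl_state_levels())
  (lo[i] + hi[i]) / 2
}

# nearest-rank percentile: smallest value with at least p% of observations at
# or below it
nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

# Wald odds-ratio table from a fitted binomial glm; aliased (NA)
# coefficients are dropped
wald_or_table <- function(fit, conf_level = 0.95) {
  est <- stats::coef(fit)
  est <- est[!is.na(est)]
  se <- sqrt(diag(stats::vcov(fit)))[names(est)]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- names(est) != "(Intercept)"
  tibble::tibble(
    term = names(est)[keep],
    or = exp(est[keep]),
    ci_lower = exp(est[keep] - z * se[keep]),
    ci_upper = exp(est[keep] + z * se[keep]),
    n = stats::nobs(fit)
  )
}
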