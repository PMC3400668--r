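# Critical swimming speed and the exponential swim-cost power curve:
# Ucrit from step protocols via Brett's equation, nonlinear fitting of
# MO2 = alpha * exp(beta * U), routine metabolic rate as the fitted
# intercept, optimal swimming speed as 1/beta, and cost of transport.

#' Critical swimming speed from a step protocol
#'
#' Brett's equation: `Ucrit = V + (t / T) * dV`, where `V` is the
#' highest speed maintained for the full period, `t` the time swum at
#' the fatigue speed, `T` the prescribed period per step and `dV` the
#' velocity increment.
#'
#' @param protocol A `step_protocol` (see [gen_ucrit_trial()]), or a
#'   list with fields `completed_speed`, `time_at_final`, `period`,
#'   `delta_v`.
#' @return Ucrit in cm s^-1.
#' @examples
#' compute_ucrit(list(completed_speed = 60, time_at_final = 15,
#'                    period = 30, delta_v = 6))  # 63
#' @export
compute_ucrit <- function(protocol) {
  v <- protocol$completed_speed
  t <- protocol$time_at_final
  T_ <- protocol$period
  dv <- protocol$delta_v
  check_positive(T_, "period")
  check_positive(dv, "delta_v")
  check_nonneg(v, "completed_speed")
  if (!is.numeric(t) || t < 0 || t >= T_) {
    stop("`time_at_final` must satisfy 0 <= t < period; a full final ",
         "period means the fish advanced a step", call. = FALSE)
  }
  v + t / T_ * dv
}

#' Fit the exponential metabolic power curve
#'
#' Nonlinear least squares for `MO2 = alpha * exp(beta * U)` on
#' untransformed rates, initialised from the log-linear regression of
#' `log(MO2)` on `U`. `alpha` is interpreted as the routine metabolic
#' rate (the curve at zero speed) and `beta` as the steepness of the
#' swimming cost; the optimal swimming speed is `1/beta`. Setting
#' `method = "loglinear"` returns the log-linear solution itself.
#'
#' @param points Data frame with columns `speed` (cm s^-1) and `mo2`
#'   (or `mo2_std`), mg O2 kg^-1 h^-1; all rates must be positive.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @return A `power_curve`: list with `alpha`, `beta`, `uopt`,
#'   `residual_sse`, `n_points`, `method`.
#' @export
fit_power_curve <- function(points, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  mo2 <- points$mo2_std %||% points$mo2
  speed <- points$speed
  if (is.null(mo2) || is.null(speed)) {
    stop("`points` needs columns `speed` and `mo2` (or `mo2_std`)",
         call. = FALSE)
  }
  ok <- is.finite(speed) & is.finite(mo2)
  speed <- speed[ok]; mo2 <- mo2[ok]
  if (length(unique(speed)) < 3L) {
    stop("need at least 3 distinct speeds to fit the power curve",
         call. = FALSE)
  }
  if (any(mo2 <= 0)) stop("all MO2 values must be positive", call. = FALSE)

  lfit <- stats::lm.fit(cbind(1, speed), log(mo2))
  start <- list(alpha = exp(lfit$coefficients[[1L]]),
                beta = lfit$coefficients[[2L]])
  if (method == "loglinear") {
    alpha <- start$alpha; beta <- start$beta
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(mo2 ~ alpha * exp(beta * speed),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop("power-curve fit failed to converge: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    cf <- stats::coef(fit)
    alpha <- cf[["alpha"]]; beta <- cf[["beta"]]
  }
  if (!is.finite(alpha) || alpha <= 0 || !is.finite(beta) || beta <= 0) {
    stop("power-curve fit produced non-positive parameters; the ",
         "MO2-speed relationship is not an increasing exponential",
         call. = FALSE)
  }
  resid <- mo2 - alpha * exp(beta * speed)
  structure(
    list(alpha = alpha, beta = beta, uopt = 1 / beta,
         residual_sse = sum(resid^2), n_points = length(speed),
         method = method),
    class = "power_curve"
  )
}

#' Evaluate a fitted power curve
#'
#' @param curve A `power_curve`.
#' @param speed Speeds, cm s^-1.
#' @return Predicted MO2, mg O2 kg^-1 h^-1.
#' @export
predict_power_curve <- function(curve, speed) {
  stopifnot(inherits(curve, "power_curve"))
  curve$alpha * exp(curve$beta * speed)
}

#' Routine metabolic rate from a fitted power curve
#'
#' The curve extrapolated to 0 cm s^-1, i.e. `alpha`.
#'
#' @param curve A `power_curve`.
#' @return RMR in mg O2 kg^-1 h^-1.
#' @export
rmr_from_fit <- function(curve) {
  stopifnot(inherits(curve, "power_curve"))
  curve$alpha
}

#' Optimal swimming speed
#'
#' The speed minimising cost of transport under the exponential model:
#' `COT(U) = alpha * exp(beta * U) / U` is minimised at `U = 1/beta`.
#'
#' @param curve A `power_curve`, or a list with a positive `beta`.
#' @return Uopt in cm s^-1.
#' @export
optimal_speed <- function(curve) {
  beta <- curve$beta
  check_positive(beta, "beta")
  1 / beta
}

#' Cost of transport
#'
#' Oxygen expended per kilogram per kilometre:
#' `COT = MO2 / U` with `U` converted from cm s^-1 to km h^-1
#' (1 cm s^-1 = 0.036 km h^-1).
#'
#' @param mo2_std Mass-standardised MO2, mg O2 kg^-1 h^-1.
#' @param speed Swimming speed, cm s^-1 (> 0).
#' @return Data frame with `speed` and `cot` (mg O2 kg^-1 km^-1).
#' @examples
#' compute_cot(360, 100)  # 100 cm/s = 3.6 km/h -> COT 100
#' @export
compute_cot <- function(mo2_std, speed) {
  if (any(!is.finite(speed)) || any(speed <= 0)) {
    stop("`speed` must be positive", call. = FALSE)
  }
  data.frame(speed = speed, cot = mo2_std / (speed * 0.036))
}

#' Relative critical swimming speed
#'
#' Ucrit expressed in body lengths per second. Group statistics in this
#' package use the absolute Ucrit; the relative form is provided for
#' completeness since it is strongly size-dependent.
#'
#' @param ucrit Absolute Ucrit, cm s^-1.
#' @param body_length_cm Body length, cm.
#' @return Ucrit in BL s^-1.
#' @export
relative_ucrit <- function(ucrit, body_length_cm) {
  check_positive(body_length_cm, "body_length_cm")
  ucrit / body_length_cm
}
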