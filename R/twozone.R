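#' @title Two-zone (near-field/far-field) dispersion model
#' @description Closed-form transient and steady-state concentrations in a
#'   two-compartment room model with a constant source in the near field,
#'   plus a numerical integrator used as an independent oracle.
#' @name twozone
NULL

#' Near-field hemisphere volume
#'
#' The near field is the hemisphere of radius `r` (default 0.6 m) around the
#' emission source, containing the welder's breathing zone:
#' \eqn{V_N = (2/3)\pi r^3}.
#'
#' @param radius Hemisphere radius (m).
#' @return Volume (m3); 0.452 m3 for the default radius.
#' @export
nf_hemisphere_volume <- function(radius = 0.6) {
  (2 / 3) * pi * radius^3
}

#' Two-zone model parameters
#'
#' @param Q Room supply air rate (m3/min), > 0.
#' @param beta Interzonal airflow between near and far field (m3/min), > 0.
#' @param V_N Near-field volume (m3), > 0; default the 0.6 m hemisphere.
#' @param V_F Far-field volume (m3), > 0.
#' @return An object of class `two_zone_params`.
#' @export
two_zone_params <- function(Q, beta, V_N = nf_hemisphere_volume(), V_F) {
  vals <- c(Q = Q, beta = beta, V_N = V_N, V_F = V_F)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all of Q, beta, V_N, V_F must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "two_zone_params")
}

#' Eigenvalues of the two-zone system
#'
#' Roots of
#' \deqn{\lambda^2 + \frac{\beta V_F + V_N(\beta+Q)}{V_N V_F}\lambda +
#'   \frac{\beta Q}{V_N V_F} = 0,}
#' both real and negative for any positive parameters. Returned with
#' `lambda1 > lambda2` (lambda1 is the slow mode). A numerically stable
#' quadratic formula avoids cancellation for widely separated roots.
#'
#' @param params A [two_zone_params()].
#' @return Named numeric vector `c(lambda1, lambda2)` (1/min).
#' @export
tz_eigenvalues <- function(params) {
  stopifnot(inherits(params, "two_zone_params"))
  b <- with(params, (beta * V_F + V_N * (beta + Q)) / (V_N * V_F))
  c0 <- with(params, beta * Q / (V_N * V_F))
  disc <- b^2 - 4 * c0
  if (disc < 0) disc <- 0  # cannot occur for positive params; guard rounding
  # stable: compute the large-magnitude root first, the other via the product
  l2 <- -(b + sqrt(disc)) / 2
  l1 <- c0 / l2
  c(lambda1 = l1, lambda2 = l2)
}

# shared coefficients of the transient solution (zero initial concentrations)
.tz_coefs <- function(params, er) {
  l <- tz_eigenvalues(params)
  l1 <- l[["lambda1"]]; l2 <- l[["lambda2"]]
  denom <- with(params, beta * Q * V_N * (l1 - l2))
  a1 <- er * with(params, beta * Q + l2 * V_N * (beta + Q)) / denom
  a2 <- er * with(params, beta * Q + l1 * V_N * (beta + Q)) / denom
  list(l1 = l1, l2 = l2, a1 = a1, a2 = a2)
}

#' Transient two-zone concentrations
#'
#' Exact closed-form concentrations at time `t` for a constant near-field
#' source switched on at `t = 0` with zero initial concentrations:
#' \deqn{C_N(t) = ER/Q + ER/\beta + A_1 e^{\lambda_1 t} - A_2 e^{\lambda_2 t}}
#' \deqn{C_F(t) = ER/Q +
#'   \frac{\lambda_1 V_N + \beta}{\beta} A_1 e^{\lambda_1 t} -
#'   \frac{\lambda_2 V_N + \beta}{\beta} A_2 e^{\lambda_2 t}}
#' When the two eigenvalues nearly coincide
#' (\eqn{|\lambda_1-\lambda_2| < 10^{-9}|\lambda_2|}) the repeated-root
#' (L'Hopital) form is used to avoid catastrophic cancellation.
#'
#' @param params A [two_zone_params()].
#' @param er Emission rate (mg/min), >= 0.
#' @param t Time since the source started (min), >= 0; vectorized.
#' @return A data.frame with columns `t`, `c_nf`, `c_ff` (mg/m3).
#' @export
tz_concentration <- function(params, er, t) {
  stopifnot(inherits(params, "two_zone_params"))
  if (er < 0) stop("er must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (er == 0) {
    return(data.frame(t = t, c_nf = 0 * t, c_ff = 0 * t))
  }
  l <- tz_eigenvalues(params)
  l1 <- l[["lambda1"]]; l2 <- l[["lambda2"]]
  ss <- tz_steady_state(params, er)
  if (abs(l1 - l2) < 1e-9 * abs(l2)) {
    # repeated-root limit: C = ss + (B0 + B1 t) e^{lambda t} with the
    # coefficients fixed by C(0) = 0 and C'(0) from the mass balance
    lam <- (l1 + l2) / 2
    b0_n <- -ss$c_nf
    b1_n <- er / params$V_N - lam * b0_n  # from dC_N/dt(0) = ER/V_N
    b0_f <- -ss$c_ff
    b1_f <- -lam * b0_f
    c_nf <- ss$c_nf + (b0_n + b1_n * t) * exp(lam * t)
    c_ff <- ss$c_ff + (b0_f + b1_f * t) * exp(lam * t)
  } else {
    co <- .tz_coefs(params, er)
    c_nf <- ss$c_nf + co$a1 * exp(l1 * t) - co$a2 * exp(l2 * t)
    c_ff <- ss$c_ff +
      (l1 * params$V_N + params$beta) / params$beta * co$a1 * exp(l1 * t) -
      (l2 * params$V_N + params$beta) / params$beta * co$a2 * exp(l2 * t)
  }
  data.frame(t = t, c_nf = pmax(c_nf, 0), c_ff = pmax(c_ff, 0))
}

#' Steady-state two-zone concentrations
#'
#' The long-time limits of the transient solution:
#' far field \eqn{ER/Q}; near field \eqn{ER/Q + ER/\beta}.
#'
#' @inheritParams tz_concentration
#' @return A list with `c_nf` and `c_ff` (mg/m3).
#' @export
tz_steady_state <- function(params, er) {
  stopifnot(inherits(params, "two_zone_params"))
  if (er < 0) stop("er must be >= 0", call. = FALSE)
  list(c_nf = er / params$Q + er / params$beta, c_ff = er / params$Q)
}

#' Shift-average concentrations under an arc duty cycle
#'
#' Maps the model to a time-weighted-average sample by the duty-cycle
#' approximation: steady state scaled by the fraction of the shift the arc
#' is on. Valid when the slow relaxation time \eqn{1/|\lambda_1|} is short
#' compared with the arc-on duration; see the methods vignette.
#'
#' @inheritParams tz_concentration
#' @param arc_minutes Arc-on time during the shift (min), > 0.
#' @param shift_minutes Shift duration (min), >= `arc_minutes`
#'   (default 480, an 8-h shift).
#' @return A list with `c_nf` and `c_ff` (mg/m3, shift TWA).
#' @export
tz_tw_average <- function(params, er, arc_minutes, shift_minutes = 480) {
  if (arc_minutes <= 0 || arc_minutes > shift_minutes) {
    stop("need 0 < arc_minutes <= shift_minutes", call. = FALSE)
  }
  ss <- tz_steady_state(params, er)
  f <- arc_minutes / shift_minutes
  list(c_nf = ss$c_nf * f, c_ff = ss$c_ff * f)
}

#' Numerical two-zone oracle
#'
#' Integrates the two-compartment mass balance
#' \deqn{V_N \, dC_N/dt = ER + \beta (C_F - C_N)}
#' \deqn{V_F \, dC_F/dt = \beta C_N - \beta C_F - Q C_F}
#' numerically (via \pkg{deSolve}), independently of the closed form.
#' With `dt = NULL` (default) the stiffness-switching adaptive integrator
#' lsoda is used at tight tolerances; an explicit `dt` forces fixed-step
#' classical Runge-Kutta instead. Used in tests to validate
#' [tz_concentration()]; agreement within 1e-6 relative is asserted there,
#' not assumed here.
#'
#' @inheritParams tz_concentration
#' @param t Single end time (min), >= 0.
#' @param dt Optional fixed Runge-Kutta step (min); must satisfy the RK4
#'   stability bound `dt <= 2 / |lambda2|`, otherwise the integrator
#'   refuses.
#' @return A list with `c_nf` and `c_ff` at time `t`.
#' @export
tz_numeric_oracle <- function(params, er, t, dt = NULL) {
  stopifnot(inherits(params, "two_zone_params"))
  if (er < 0 || t < 0) stop("er and t must be >= 0", call. = FALSE)
  if (t == 0) return(list(c_nf = 0, c_ff = 0))
  deriv <- function(time, y, parms) {
    list(c(
      (er + params$beta * (y[2] - y[1])) / params$V_N,
      (params$beta * y[1] - params$beta * y[2] - params$Q * y[2]) / params$V_F
    ))
  }
  if (is.null(dt)) {
    scale <- max(er / params$Q + er / params$beta, 1e-12)
    out <- deSolve::lsoda(y = c(0, 0), times = c(0, t), func = deriv,
                          parms = NULL, rtol = 1e-10,
                          atol = 1e-12 * scale)
  } else {
    l2 <- tz_eigenvalues(params)[["lambda2"]]
    if (dt > 2 / abs(l2)) {
      stop(sprintf(
        "dt = %g exceeds the RK4 stability bound 2/|lambda2| = %g",
        dt, 2 / abs(l2)), call. = FALSE)
    }
    times <- sort(unique(c(seq(0, t, by = dt), t)))
    out <- deSolve::ode(y = c(0, 0), times = times, func = deriv,
                        parms = NULL, method = "rk4")
  }
  last <- out[nrow(out), ]
  list(c_nf = unname(last[2]), c_ff = unname(last[3]))
}

#' Interzonal airflow from wind speed (optional helper)
#'
#' The textbook estimate \eqn{\beta = \tfrac{1}{2} s \cdot FSA} with
#' \eqn{FSA = 2\pi r^2} the free surface area of the near-field hemisphere
#' and `s` the random air speed. Provided for completeness but not used by
#' default: field interzonal flows are supplied directly because this
#' back-of-envelope formula can differ several-fold from anemometer-derived
#' values in naturally ventilated halls.
#'
#' @param speed_m_s Air speed (m/s).
#' @param radius Near-field hemisphere radius (m).
#' @return beta (m3/min).
#' @export
beta_from_windspeed <- function(speed_m_s, radius = 0.6) {
  if (speed_m_s < 0) stop("speed must be >= 0", call. = FALSE)
  0.5 * (speed_m_s * 60) * (2 * pi * radius^2)
}
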