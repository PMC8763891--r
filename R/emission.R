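#' @title Chamber emission-rate estimation
#' @description Forward mass-balance simulation of a fume test chamber and
#'   the simplified peak-rise estimator of the fume emission rate.
#' @name emission
NULL

#' Construct a chamber concentration series
#'
#' @param times Sampling times (min), strictly increasing, length >= 2.
#' @param c_in In-chamber concentrations (mg/m3), non-negative.
#' @param volume Effective chamber volume V (m3), > 0.
#' @param aer Air exchange rate (1/min), >= 0.
#' @param k Particle deposition rate (1/min), >= 0 (default 0; the removal
#'   rate supplied with a series is taken as given, see [fit_removal_rate()]
#'   to estimate it from the decay tail).
#' @param p Penetration efficiency of outdoor particles, in \[0, 1\].
#' @param c_out Outdoor (make-up air) concentration (mg/m3), scalar or one
#'   value per time.
#' @return An object of class `chamber_series`.
#' @export
chamber_series <- function(times, c_in, volume, aer, k = 0, p = 1, c_out = 0) {
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(c_in) != length(times)) {
    stop("c_in must match times in length", call. = FALSE)
  }
  if (any(c_in < 0)) stop("negative concentrations", call. = FALSE)
  if (volume <= 0) stop("volume must be > 0", call. = FALSE)
  if (aer < 0 || k < 0) stop("aer and k must be >= 0", call. = FALSE)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (!length(c_out) %in% c(1L, length(times)) || any(c_out < 0)) {
    stop("c_out must be a non-negative scalar or per-time vector",
         call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), c_in = as.numeric(c_in),
         volume = volume, aer = aer, k = k, p = p, c_out = c_out),
    class = "chamber_series"
  )
}

#' Simulate a chamber concentration trace from a known emission rate
#'
#' Solves the single-compartment mass balance
#' \deqn{dC/dt = p \cdot AER \cdot C_{out} + Q_s/V - (AER + k) C}
#' with \eqn{Q_s = ER} while the arc is on and 0 afterwards. Each
#' piecewise-constant segment is solved analytically (exponential relaxation
#' towards the segment's equilibrium), not by crude stepping. The removal
#' term carries a negative sign so that air exchange and deposition reduce
#' the concentration.
#'
#' @param er_true True emission rate (mg/min), >= 0.
#' @param volume,aer,k,p,c_out Chamber parameters as in [chamber_series()].
#' @param arc_minutes Arc-on duration (min); the source is on over
#'   \[0, arc_minutes\].
#' @param duration Total simulated duration (min), >= `dt`.
#' @param dt Output sampling interval (min), > 0.
#' @param c0 Initial in-chamber concentration (mg/m3).
#' @return A `chamber_series` whose `c_in` is the exact solution sampled at
#'   `seq(0, duration, by = dt)` (plus the arc-off breakpoint).
#' @export
simulate_chamber_series <- function(er_true, volume, aer, k = 0, p = 1,
                                    c_out = 0, arc_minutes = 0.5,
                                    duration = 5, dt = 0.01, c0 = 0) {
  if (er_true < 0) stop("er_true must be >= 0", call. = FALSE)
  if (dt <= 0 || duration < dt) {
    stop("need dt > 0 and duration >= dt", call. = FALSE)
  }
  if (arc_minutes < 0 || arc_minutes > duration) {
    stop("arc_minutes must lie in [0, duration]", call. = FALSE)
  }
  times <- sort(unique(c(seq(0, duration, by = dt), arc_minutes, duration)))
  r <- aer + k
  relax <- function(c_start, source, t) {
    a <- p * aer * c_out + source / volume
    if (r == 0) return(c_start + a * t)
    ceq <- a / r
    ceq + (c_start - ceq) * exp(-r * t)
  }
  on_idx <- times <= arc_minutes
  c_in <- numeric(length(times))
  c_in[on_idx] <- relax(c0, er_true, times[on_idx])
  c_arc_end <- relax(c0, er_true, arc_minutes)
  c_in[!on_idx] <- relax(c_arc_end, 0, times[!on_idx] - arc_minutes)
  chamber_series(times, pmax(c_in, 0), volume, aer, k, p, c_out)
}

#' Estimate the emission rate from a chamber trace
#'
#' Implements the simplified peak-rise mass-balance estimator
#' \deqn{ER = V [ C_{in}/\Delta t + (AER + k) \bar{C}_{in} ]}
#' where \eqn{C_{in}} is the peak concentration, \eqn{\Delta t} the time
#' from the start of the series to the peak, and \eqn{\bar{C}_{in}} the
#' (trapezoidal) mean concentration over \[0, peak\]. `method = "full"`
#' retains the initial concentration:
#' \deqn{ER = V [ (C_{in} - C_{in,0})/\Delta t + (AER + k) \bar{C}_{in}
#'   - AER \cdot C_{in,0} ]}
#' which should be preferred whenever the trace does not start at zero.
#'
#' The peak is the global maximum; ties are broken by the earliest time,
#' except that the series origin itself is never used as the peak (a trace
#' whose unique maximum is the first sample is a degenerate input).
#'
#' @param series A [chamber_series()].
#' @param method `"simplified"` (drop the initial-concentration terms) or
#'   `"full"`.
#' @param metal,process,wire,current Optional condition labels.
#' @return An object of class `emission_estimate`: list with `er` (mg/min),
#'   `cv` (NA for a single trace), `n = 1`, `zero_trace` flag and the
#'   condition labels.
#' @export
estimate_emission_rate <- function(series,
                                   method = c("simplified", "full"),
                                   metal = NA_character_,
                                   process = NA_character_,
                                   wire = NA_character_,
                                   current = NA_real_) {
  method <- match.arg(method)
  stopifnot(inherits(series, "chamber_series"))
  tt <- series$times - series$times[1]
  cc <- series$c_in
  if (all(cc == 0)) {
    warning("all-zero concentration trace; returning er = 0", call. = FALSE)
    return(structure(
      list(er = 0, cv = NA_real_, n = 1L, zero_trace = TRUE, method = method,
           metal = metal, process = process, wire = wire, current = current),
      class = "emission_estimate"))
  }
  cand <- which(cc == max(cc))
  cand <- setdiff(cand, 1L)
  if (!length(cand)) {
    stop("peak concentration at t = 0: degenerate input", call. = FALSE)
  }
  ipk <- cand[1]
  c_pk <- cc[ipk]
  delta_t <- tt[ipk]
  # trapezoidal time-weighted mean over [0, peak]
  seg <- seq_len(ipk)
  cbar <- sum(diff(tt[seg]) * (cc[seg][-1] + cc[seg][-ipk]) / 2) / delta_t
  r <- series$aer + series$k
  er <- if (method == "simplified") {
    series$volume * (c_pk / delta_t + r * cbar)
  } else {
    c0 <- cc[1]
    series$volume * ((c_pk - c0) / delta_t + r * cbar - series$aer * c0)
  }
  structure(
    list(er = er, cv = NA_real_, n = 1L, zero_trace = FALSE, method = method,
         metal = metal, process = process, wire = wire, current = current),
    class = "emission_estimate")
}

#' Fit the removal rate from the post-peak decay
#'
#' After the arc stops (and with negligible make-up air concentration) the
#' chamber concentration decays as \eqn{C(t) \propto e^{-(AER+k)t}};
#' a log-linear regression of the post-peak tail therefore estimates the
#' combined removal rate AER + k for users who did not measure it.
#'
#' @param series A [chamber_series()].
#' @param min_points Minimum number of post-peak points required.
#' @return The estimated removal rate (1/min).
#' @export
fit_removal_rate <- function(series, min_points = 3L) {
  stopifnot(inherits(series, "chamber_series"))
  ipk <- which.max(series$c_in)
  idx <- seq(ipk, length(series$times))
  idx <- idx[series$c_in[idx] > 0]
  if (length(idx) < min_points) {
    stop("not enough positive post-peak points to fit the decay",
         call. = FALSE)
  }
  fit <- stats::lm(log(c_in) ~ times,
                   data = data.frame(times = series$times[idx],
                                     c_in = series$c_in[idx]))
  -unname(stats::coef(fit)[2])
}

#' Pool replicate emission estimates for one welding condition
#'
#' @param estimates A list of `emission_estimate` objects sharing the same
#'   metal/process/wire/current condition.
#' @return An `emission_estimate` with `er` the arithmetic mean, `cv` the
#'   coefficient of variation (sample SD with n-1 denominator over the mean;
#'   `NA` for a single replicate) and `n` the replicate count.
#' @export
summarize_replicates <- function(estimates) {
  if (!length(estimates)) stop("no estimates supplied", call. = FALSE)
  if (inherits(estimates, "emission_estimate")) estimates <- list(estimates)
  stopifnot(all(vapply(estimates, inherits, logical(1), "emission_estimate")))
  key <- function(e) paste(e$metal, e$process, e$wire, e$current, sep = "|")
  keys <- vapply(estimates, key, character(1))
  if (length(unique(keys)) != 1L) {
    stop("estimates mix welding conditions: ",
         paste(unique(keys), collapse = " vs "), call. = FALSE)
  }
  ers <- vapply(estimates, function(e) e$er, numeric(1))
  m <- mean(ers)
  cv <- if (length(ers) >= 2) stats::sd(ers) / m else NA_real_
  out <- estimates[[1]]
  out$er <- m
  out$cv <- cv
  out$n <- length(ers)
  out
}

#' @export
print.emission_estimate <- function(x, ...) {
  cat(sprintf("<emission_estimate> %s %s/%s %sA  ER = %.4g mg/min  CV = %s  n = %d\n",
              x$metal, x$process, x$wire, format(x$current), x$er,
              ifelse(is.na(x$cv), "NA", sprintf("%.3g", x$cv)), x$n))
  invisible(x)
}
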