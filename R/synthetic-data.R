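#' @title Synthetic study-input generators
#' @description Seeded generators that emulate every input of the shipyard
#'   exposure study: daily operation records and lognormal exposure samples
#'   with optional left-censoring at a limit of quantification (LOQ).
#' @name synthetic-data
NULL

# Shipyard processes and their wires; FCAW wires are KFX*, GMAW wires are KM*.
.wf_processes <- c("FCAW", "GMAW")
.wf_wires <- list(FCAW = c("KFX71T", "KFX70T"), GMAW = c("KM56", "KM58"))
.wf_currents <- c(120, 220, 300)
.wf_metals <- c("Cr", "Fe", "Mn", "Ni", "Pb")

#' Default parameter ranges for synthetic operation records
#'
#' Interzonal airflow (beta) ranges are the per-process field ranges observed
#' in the study setting: 6.78--11.1 m3/min for FCAW and 5.11--9.08 m3/min for
#' GMAW. The remaining ranges are stated defaults for a naturally ventilated
#' shipyard welding bay (see the methods vignette): room supply air rate Q in
#' 20--60 m3/min, near-field volume fixed at the 0.6 m-radius hemisphere
#' (0.452 m3), far-field volume 100--1000 m3, and arc duty cycle 0.25--0.75
#' of the shift.
#'
#' @return A named list of `c(low, high)` numeric ranges for `beta_fcaw`,
#'   `beta_gmaw`, `Q`, `V_N`, `V_F` and `duty_cycle`.
#' @export
default_param_ranges <- function() {
  list(
    beta_fcaw  = c(6.78, 11.1),
    beta_gmaw  = c(5.11, 9.08),
    Q          = c(20, 60),
    V_N        = c(nf_hemisphere_volume(), nf_hemisphere_volume()),
    V_F        = c(100, 1000),
    duty_cycle = c(0.25, 0.75)
  )
}

.check_range <- function(r, name, positive = TRUE) {
  if (!is.numeric(r) || length(r) != 2 || anyNA(r)) {
    stop("range '", name, "' must be a numeric c(low, high)", call. = FALSE)
  }
  if (r[1] > r[2]) stop("range '", name, "' has low > high", call. = FALSE)
  if (positive && r[1] <= 0) {
    stop("range '", name, "' must be strictly positive", call. = FALSE)
  }
  invisible(r)
}

# Draw n values from a range: uniform, or symmetric triangular on [low, high].
.draw_range <- function(n, r, distribution = "uniform") {
  if (r[1] == r[2]) return(rep(r[1], n))
  if (distribution == "triangular") {
    u <- stats::runif(n)
    lo <- r[1]; hi <- r[2]; mode <- (lo + hi) / 2
    fc <- (mode - lo) / (hi - lo)
    ifelse(u < fc,
           lo + sqrt(u * (hi - lo) * (mode - lo)),
           hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  } else {
    stats::runif(n, r[1], r[2])
  }
}

#' Generate synthetic daily welding operation records
#'
#' Emulates the daily operation log of a shipyard welding bay: one record per
#' working day carrying the process, wire, current and the two-zone model
#' parameters for that day. Process/wire pairing is always consistent (KFX
#' wires with FCAW, KM wires with GMAW) and the interzonal flow beta is drawn
#' within the per-process range.
#'
#' @param n_days Number of working days (>= 1).
#' @param param_ranges Named list of `c(low, high)` ranges as returned by
#'   [default_param_ranges()]; entries may be overridden selectively.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param p_fcaw Probability a day uses FCAW (default 2/3, the field split of
#'   12 FCAW vs 6 GMAW welders).
#' @param distribution Either `"uniform"` (default) or `"triangular"` for the
#'   within-range parameter draws.
#' @return A data.frame with one row per day and columns `day_index`,
#'   `process`, `wire`, `current`, `Q`, `beta`, `V_N`, `V_F`, `duty_cycle`.
#' @examples
#' recs <- gen_operation_records(25, seed = 1)
#' range(recs$beta)  # within [5.11, 11.1]
#' @export
gen_operation_records <- function(n_days,
                                  param_ranges = default_param_ranges(),
                                  seed = 1L,
                                  p_fcaw = 2 / 3,
                                  distribution = c("uniform", "triangular")) {
  distribution <- match.arg(distribution)
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1) {
    stop("n_days must be a single integer >= 1", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  ranges <- utils::modifyList(default_param_ranges(), as.list(param_ranges))
  for (nm in c("beta_fcaw", "beta_gmaw", "Q", "V_N", "V_F")) {
    .check_range(ranges[[nm]], nm)
  }
  .check_range(ranges$duty_cycle, "duty_cycle")
  if (ranges$duty_cycle[2] > 1) {
    stop("duty_cycle range must lie within (0, 1]", call. = FALSE)
  }

  set.seed(as.integer(seed))
  process <- ifelse(stats::runif(n_days) < p_fcaw, "FCAW", "GMAW")
  wire <- vapply(process, function(p) sample(.wf_wires[[p]], 1L), character(1))
  current <- sample(.wf_currents, n_days, replace = TRUE)
  beta <- numeric(n_days)
  is_f <- process == "FCAW"
  beta[is_f] <- .draw_range(sum(is_f), ranges$beta_fcaw, distribution)
  beta[!is_f] <- .draw_range(sum(!is_f), ranges$beta_gmaw, distribution)

  data.frame(
    day_index = seq_len(n_days),
    process = process,
    wire = wire,
    current = current,
    Q = .draw_range(n_days, ranges$Q, distribution),
    beta = beta,
    V_N = .draw_range(n_days, ranges$V_N, distribution),
    V_F = .draw_range(n_days, ranges$V_F, distribution),
    duty_cycle = .draw_range(n_days, ranges$duty_cycle, distribution),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Generate a lognormal exposure sample with optional left-censoring
#'
#' Draws `n` concentrations from a lognormal distribution with geometric mean
#' `gm` and geometric standard deviation `gsd`, flags values below the LOQ as
#' censored, and stores the generating truth for recovery tests.
#'
#' @param gm Geometric mean (mg/m3), > 0.
#' @param gsd Geometric standard deviation, >= 1 (`gsd = 1` gives a
#'   zero-variance sample, all values exactly `gm`).
#' @param n Sample size (>= 1).
#' @param loq Limit of quantification (mg/m3); values strictly below it are
#'   flagged censored. `loq = 0` (default) disables censoring. Censored
#'   observations keep their true simulated value in `true_values`.
#' @param seed Integer seed.
#' @param metal,zone Optional labels carried through to the output.
#' @return An object of class `exposure_dataset`: a list with `values`
#'   (censored values substituted at the LOQ), `true_values`, `censored`
#'   (logical), `n`, `gm`, `gsd` (empirical, from the uncensored true
#'   values), `truth` (`gm`, `gsd`, `seed` requested), `loq`,
#'   `fully_censored`, `provenance = "synthetic"`, `metal`, `zone`.
#' @export
gen_lognormal_sample <- function(gm, gsd, n, loq = 0, seed = 1L,
                                 metal = NA_character_, zone = NA_character_) {
  if (!is.numeric(gm) || gm <= 0) stop("gm must be > 0", call. = FALSE)
  if (!is.numeric(gsd) || gsd < 1) stop("gsd must be >= 1", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (loq < 0) stop("loq must be >= 0", call. = FALSE)
  n <- as.integer(n)

  set.seed(as.integer(seed))
  x <- if (gsd == 1) rep(gm, n) else stats::rlnorm(n, log(gm), log(gsd))
  cens <- x < loq
  obs <- ifelse(cens, loq, x)

  summ <- lognormal_summary(x)
  structure(
    list(
      values = obs,
      true_values = x,
      censored = cens,
      n = n,
      gm = summ[["gm"]],
      gsd = summ[["gsd"]],
      truth = list(gm = gm, gsd = gsd, seed = as.integer(seed)),
      loq = loq,
      fully_censored = all(cens),
      provenance = "synthetic",
      metal = metal,
      zone = zone
    ),
    class = "exposure_dataset"
  )
}

#' @export
print.exposure_dataset <- function(x, ...) {
  cat(sprintf(
    "<exposure_dataset> %s/%s  n = %d  GM = %.4g  GSD = %.3g  (%s)\n",
    x$metal, x$zone, x$n, x$gm, x$gsd, x$provenance))
  if (any(x$censored)) {
    cat(sprintf("  %d of %d values below LOQ = %g\n",
                sum(x$censored), x$n, x$loq))
  }
  invisible(x)
}
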