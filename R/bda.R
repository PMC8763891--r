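#' @title Bayesian decision analysis for exposure ratings
#' @description Grid-based Bayesian decision analysis on the lognormal
#'   (GM, GSD) parameter plane: a prior encoded from the model-predicted
#'   long-term distribution, a lognormal likelihood from field sufficient
#'   statistics, and posterior exposure-rating decision charts (ER0-ER4)
#'   with action-level exceedance.
#' @name bda
NULL

.wf_default_oels <- c(Cr = 0.5, Fe = 10, Mn = 0.1, Ni = 1, Pb = 0.05)
.wf_controls <- c(
  "no action",
  "general hazardous communication",
  "chemical-specific hazardous communication",
  "exposure surveillance/medical surveillance/work practices",
  "respirators/work practice controls")

#' Exposure-rating scheme
#'
#' Five ordered rating bands defined as fractions of the occupational
#' exposure limit (OEL): ER0 <= 0.005 OEL, 0.005 OEL < ER1 <= 0.05 OEL,
#' 0.05 OEL < ER2 <= 0.25 OEL, 0.25 OEL < ER3 <= 0.5 OEL, ER4 > 0.5 OEL.
#' One-half the OEL (the top band edge) is the action level. Default OELs
#' are the 8-h TLV-TWAs: Cr 0.5, Fe 10, Mn 0.1 (inhalable), Ni 1, Pb 0.05
#' mg/m3.
#'
#' @param oels Named numeric vector of OELs (mg/m3) per metal.
#' @param band_edges Strictly increasing fractions of the OEL in (0, 1);
#'   exactly four, closing bands ER0..ER3 on the right.
#' @param control_labels Five control recommendations, one per band.
#' @return An object of class `rating_scheme`.
#' @export
rating_scheme <- function(oels = .wf_default_oels,
                          band_edges = c(0.005, 0.05, 0.25, 0.5),
                          control_labels = .wf_controls) {
  if (is.null(names(oels)) || any(oels <= 0)) {
    stop("oels must be a named vector of positive limits", call. = FALSE)
  }
  if (length(band_edges) != 4 || is.unsorted(band_edges, strictly = TRUE) ||
      band_edges[1] <= 0 || band_edges[4] >= 1) {
    stop("band_edges must be 4 strictly increasing fractions in (0, 1)",
         call. = FALSE)
  }
  if (length(control_labels) != 5) {
    stop("need exactly 5 control labels", call. = FALSE)
  }
  structure(
    list(oels = oels, band_edges = band_edges,
         action_level_fraction = band_edges[4],
         control_labels = control_labels),
    class = "rating_scheme")
}

#' Lognormal 95th percentile (the rating statistic)
#'
#' \eqn{X_{95} = GM \cdot GSD^{1.645}}, the conventional decision statistic
#' compared against the OEL in rating-chart frameworks. The arithmetic mean
#' \eqn{GM \exp(\ln(GSD)^2/2)} is available as an auditable alternative.
#'
#' @param gm Geometric mean (mg/m3), > 0.
#' @param gsd Geometric standard deviation, >= 1.
#' @param statistic `"x95"` (default) or `"am"`.
#' @return The statistic (mg/m3); vectorized.
#' @export
rating_statistic <- function(gm, gsd, statistic = c("x95", "am")) {
  statistic <- match.arg(statistic)
  if (any(gm <= 0)) stop("gm must be > 0", call. = FALSE)
  if (any(gsd < 1)) stop("gsd must be >= 1", call. = FALSE)
  if (statistic == "x95") gm * gsd^1.645
  else gm * exp(log(gsd)^2 / 2)
}

#' Rating band of a statistic value
#'
#' Bands are half-open on the left with inclusive upper edges, exactly as
#' defined: a value on an edge belongs to the lower band (e.g. a ratio of
#' exactly 0.5 is ER3; anything above is ER4).
#'
#' @param x Statistic value(s) (mg/m3).
#' @param oel The OEL (mg/m3), > 0.
#' @param scheme A [rating_scheme()].
#' @return Integer band index/indices in 0..4.
#' @export
band_of <- function(x, oel, scheme = rating_scheme()) {
  if (oel <= 0) stop("oel must be > 0", call. = FALSE)
  ratio <- x / oel
  findInterval(ratio, scheme$band_edges, left.open = TRUE)
}

#' Geometric (GM, GSD) parameter grid
#'
#' The discretization behind the decision charts: geometric node sequences
#' in GM and GSD with one weight per (GM, GSD) node. Default bounds span
#' OEL x 10^-3 to OEL x 10^2 in GM (401 nodes) and 1.01 to 4.5 in GSD
#' (201 nodes), wide enough to cover typical workplace statistics with
#' margin.
#'
#' @param oel The OEL anchoring the GM range (mg/m3).
#' @param gm_range,gsd_range Length-2 bounds.
#' @param n_gm,n_gsd Node counts.
#' @return An object of class `param_grid`: vectors `mu` (= log GM),
#'   `sigma` (= log GSD) over all nodes (GM varying fastest), uniform
#'   `weights` summing to 1, and the node counts.
#' @export
param_grid <- function(oel, gm_range = oel * c(1e-3, 1e2), n_gm = 401,
                       gsd_range = c(1.01, 4.5), n_gsd = 201) {
  if (any(gm_range <= 0) || gm_range[1] >= gm_range[2]) {
    stop("gm_range must be positive and increasing", call. = FALSE)
  }
  if (gsd_range[1] <= 1 || gsd_range[1] >= gsd_range[2]) {
    stop("gsd_range must be increasing with lower bound > 1", call. = FALSE)
  }
  # geometric node sequences: arithmetic in log(GM) and log(GSD)
  mu_nodes <- seq(log(gm_range[1]), log(gm_range[2]), length.out = n_gm)
  sig_nodes <- seq(log(gsd_range[1]), log(gsd_range[2]),
                   length.out = n_gsd)
  grid <- expand.grid(mu = mu_nodes, sigma = sig_nodes)
  n <- nrow(grid)
  structure(
    list(mu = grid$mu, sigma = grid$sigma,
         weights = rep(1 / n, n), n_gm = n_gm, n_gsd = n_gsd,
         oel = oel),
    class = "param_grid")
}

#' Lognormal log-likelihood over a parameter grid
#'
#' Exact log-likelihood of a lognormal sample from its sufficient
#' statistics. With \eqn{m = \ln GM}, \eqn{s = \ln GSD} (n-1 denominator)
#' and node \eqn{(\mu, \sigma)}:
#' \deqn{\ell = -n \ln\sigma -
#'   \frac{(n-1)s^2 + n(m-\mu)^2}{2\sigma^2} + \mathrm{const.}}
#'
#' @param stats A list or named vector with `gm`, `gsd`, `n` (`n >= 2`;
#'   `gsd = 1` is permitted and yields a likelihood driven by the mean
#'   term only).
#' @param grid A [param_grid()].
#' @return Numeric vector of log-likelihood values, one per node (constant
#'   terms omitted).
#' @export
grid_loglik <- function(stats, grid) {
  stopifnot(inherits(grid, "param_grid"))
  stats <- as.list(stats)
  if (!all(c("gm", "gsd", "n") %in% names(stats))) {
    stop("stats needs gm, gsd and n", call. = FALSE)
  }
  if (stats$gm <= 0 || stats$gsd < 1 || stats$n < 2) {
    stop("invalid sufficient statistics (need gm > 0, gsd >= 1, n >= 2)",
         call. = FALSE)
  }
  m <- log(stats$gm); s <- log(stats$gsd); n <- stats$n
  -n * log(grid$sigma) -
    ((n - 1) * s^2 + n * (m - grid$mu)^2) / (2 * grid$sigma^2)
}

# normalize log-weights safely (log-sum-exp)
.norm_logw <- function(lw) {
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Encode a prior over the parameter grid from a predicted dataset
#'
#' Default (`mode = "suffstat"`): prior weights proportional to the
#' lognormal likelihood of the predicted dataset's sufficient statistics
#' (GM, GSD, n), treating the model-predicted long-term distribution as if
#' it were n days of observation. `mode = "uniform"` returns equal weights.
#' A degenerate predicted GSD of exactly 1 concentrates the prior in a
#' narrow ridge around the predicted GM (the likelihood then constrains
#' only the mean); the result is flagged.
#'
#' @param predicted A list/row with `gm`, `gsd`, `n` (e.g. one row of a
#'   predicted long-term summary table).
#' @param grid A [param_grid()].
#' @param mode `"suffstat"` (default) or `"uniform"`.
#' @return The grid with its `weights` replaced; attribute
#'   `"degenerate_gsd"` is TRUE when the predicted GSD was 1.
#' @export
prior_from_dataset <- function(predicted, grid,
                               mode = c("suffstat", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "param_grid"))
  if (mode == "uniform") {
    grid$weights <- rep(1 / length(grid$mu), length(grid$mu))
    return(grid)
  }
  predicted <- as.list(predicted)
  degenerate <- predicted$gsd == 1
  grid$weights <- .norm_logw(grid_loglik(predicted, grid))
  attr(grid, "degenerate_gsd") <- degenerate
  grid
}

#' Decision chart from grid weights
#'
#' Aggregates the grid weights into the five rating-band probabilities:
#' p\[k\] is the total weight of nodes whose rating statistic falls in
#' band k.
#'
#' @param grid A [param_grid()] with normalized weights.
#' @param oel The OEL (mg/m3).
#' @param scheme A [rating_scheme()].
#' @param role `"prior"`, `"likelihood"` or `"posterior"`.
#' @param metal,zone Optional labels.
#' @param statistic Passed to [rating_statistic()].
#' @return An object of class `decision_chart`: `p` (named ER0..ER4,
#'   summing to 1), `dominant_band`, `p_exceed_action` (= p\[ER4\]),
#'   `recommended_control`, plus the labels.
#' @export
decision_chart <- function(grid, oel, scheme = rating_scheme(),
                           role = "posterior", metal = NA_character_,
                           zone = NA_character_, statistic = "x95") {
  stopifnot(inherits(grid, "param_grid"))
  w <- grid$weights / sum(grid$weights)
  stat <- rating_statistic(exp(grid$mu), exp(grid$sigma), statistic)
  bands <- band_of(stat, oel, scheme)
  p <- vapply(0:4, function(k) sum(w[bands == k]), numeric(1))
  names(p) <- paste0("ER", 0:4)
  dom <- unname(which.max(p)) - 1L
  structure(
    list(metal = metal, zone = zone, role = role, p = p,
         dominant_band = dom, p_exceed_action = unname(p["ER4"]),
         recommended_control = scheme$control_labels[dom + 1L],
         oel = oel),
    class = "decision_chart")
}

#' @export
print.decision_chart <- function(x, ...) {
  cat(sprintf("<decision_chart> %s %s (%s, OEL %g mg/m3)\n",
              x$metal, x$zone, x$role, x$oel))
  cat(sprintf("  %s\n", paste(sprintf("%s %5.1f%%", names(x$p), 100 * x$p),
                              collapse = "  ")))
  cat(sprintf("  dominant ER%d -> %s; P(> action level) = %.1f%%\n",
              x$dominant_band, x$recommended_control,
              100 * x$p_exceed_action))
  invisible(x)
}

#' Prior, likelihood and posterior decision charts
#'
#' Bayesian update on the parameter grid. Under the default
#' `encoding = "suffstat"` the posterior weights are proportional to the
#' prior weights times the lognormal likelihood of the field sufficient
#' statistics (guarded by log-sum-exp). Under `encoding = "category"` the
#' update happens at the level of the five band probabilities instead:
#' posterior band probabilities proportional to prior chart times
#' likelihood chart, band-wise. The likelihood chart always uses a uniform
#' prior.
#'
#' @param prior A `param_grid` with prior weights (see
#'   [prior_from_dataset()]).
#' @param field_stats List/row with `gm`, `gsd`, `n` of the field sample.
#' @param oel The OEL (mg/m3).
#' @param scheme A [rating_scheme()].
#' @param encoding `"suffstat"` (default) or `"category"`.
#' @param metal,zone Optional labels.
#' @param statistic Passed to [rating_statistic()].
#' @return A list of three `decision_chart`s: `prior`, `likelihood`,
#'   `posterior`. The posterior grid weights are attached as attribute
#'   `"posterior_grid"` (suffstat encoding only).
#' @export
posterior_chart <- function(prior, field_stats, oel,
                            scheme = rating_scheme(),
                            encoding = c("suffstat", "category"),
                            metal = NA_character_, zone = NA_character_,
                            statistic = "x95") {
  encoding <- match.arg(encoding)
  stopifnot(inherits(prior, "param_grid"))
  ll_field <- grid_loglik(field_stats, prior)

  lik_grid <- prior
  lik_grid$weights <- .norm_logw(ll_field)

  prior_chart <- decision_chart(prior, oel, scheme, "prior", metal, zone,
                                statistic)
  lik_chart <- decision_chart(lik_grid, oel, scheme, "likelihood", metal,
                              zone, statistic)

  if (encoding == "suffstat") {
    post_grid <- prior
    lw <- log(pmax(prior$weights, .Machine$double.xmin)) + ll_field
    post_grid$weights <- .norm_logw(lw)
    post_chart <- decision_chart(post_grid, oel, scheme, "posterior",
                                 metal, zone, statistic)
    out <- list(prior = prior_chart, likelihood = lik_chart,
                posterior = post_chart)
    attr(out, "posterior_grid") <- post_grid
  } else {
    p <- prior_chart$p * lik_chart$p
    if (sum(p) == 0) {
      stop("prior and likelihood charts share no band mass; ",
           "category encoding is undefined", call. = FALSE)
    }
    p <- p / sum(p)
    dom <- unname(which.max(p)) - 1L
    post_chart <- structure(
      list(metal = metal, zone = zone, role = "posterior", p = p,
           dominant_band = dom, p_exceed_action = unname(p["ER4"]),
           recommended_control = scheme$control_labels[dom + 1L],
           oel = oel),
      class = "decision_chart")
    out <- list(prior = prior_chart, likelihood = lik_chart,
                posterior = post_chart)
  }
  out
}

#' Monte-Carlo sampling oracle for a decision chart
#'
#' Samples grid nodes according to their weights and re-derives the band
#' probabilities one draw at a time (per-draw statistic and band lookup),
#' an independent path through the band logic used to validate
#' [decision_chart()] aggregation in tests.
#'
#' @param grid A `param_grid` with normalized weights.
#' @param oel,scheme,statistic As in [decision_chart()].
#' @param n_draw Number of draws.
#' @param seed Integer seed.
#' @return Named numeric vector of five sampled band probabilities.
#' @export
sample_chart <- function(grid, oel, scheme = rating_scheme(),
                         n_draw = 1e6, seed = 1L, statistic = "x95") {
  stopifnot(inherits(grid, "param_grid"))
  set.seed(as.integer(seed))
  idx <- sample.int(length(grid$mu), n_draw, replace = TRUE,
                    prob = grid$weights)
  b <- band_of(rating_statistic(exp(grid$mu[idx]), exp(grid$sigma[idx]),
                                statistic), oel, scheme)
  tb <- tabulate(b + 1L, nbins = 5L) / n_draw
  names(tb) <- paste0("ER", 0:4)
  tb
}

#' Pool lognormal sufficient statistics of two samples
#'
#' Combines (gm1, gsd1, n1) and (gm2, gsd2, n2) into the sufficient
#' statistics of the pooled sample; used by the sequential-updating
#' identity of the grid posterior.
#'
#' @param a,b Lists with `gm`, `gsd`, `n`.
#' @return A list with pooled `gm`, `gsd`, `n`.
#' @export
pool_stats <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  n <- a$n + b$n
  m1 <- log(a$gm); m2 <- log(b$gm)
  m <- (a$n * m1 + b$n * m2) / n
  ss <- (a$n - 1) * log(a$gsd)^2 + a$n * (m1 - m)^2 +
    (b$n - 1) * log(b$gsd)^2 + b$n * (m2 - m)^2
  list(gm = exp(m), gsd = exp(sqrt(ss / (n - 1))), n = n)
}
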