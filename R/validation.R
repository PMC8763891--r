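#' @title Predicted-vs-measured validation statistics
#' @description Ordinary least-squares regression of measured on predicted
#'   concentrations and Spearman rank correlation between zone
#'   concentration sets.
#' @name validation
NULL

#' Simple linear regression of measured on predicted concentrations
#'
#' Ordinary least squares with intercept, `measured = slope * predicted +
#' intercept`, fitted via [stats::lm()]; the slope p-value is the two-sided
#' t test.
#'
#' @param x Predicted concentrations (mg/m3).
#' @param y Measured concentrations (mg/m3), same length.
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope), `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("x is constant: degenerate regression design", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         n = length(x)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> y = %.4g x + %.4g   R2 = %.3f  p = %.3g  n = %d\n",
    x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Spearman rank correlation with average-rank ties
#'
#' Rho is the Pearson correlation of the average ranks; the p-value uses
#' the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2
#' degrees of freedom (two-sided). For rho of +/- 1 the p-value is
#' reported as 0.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Regression fit table over metals and zones
#'
#' Fits [fit_linear()] for every requested grouping of a paired
#' predicted/measured table and reports all groupings; the study design
#' pools currents and wires within a metal and zone.
#'
#' @param paired Data.frame with columns `metal`, `zone`, `c_p` (predicted)
#'   and `c_m` (measured).
#' @param by Character vector of grouping columns (default
#'   `c("metal", "zone")`).
#' @return A data.frame with one row per group: the grouping columns plus
#'   `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
fit_table <- function(paired, by = c("metal", "zone")) {
  req <- c(by, "c_p", "c_m")
  if (!all(req %in% names(paired))) {
    stop("paired table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(paired[, by, drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(paired))
    for (b in by) sel <- sel & paired[[b]] == groups[[b]][i]
    f <- fit_linear(paired$c_p[sel], paired$c_m[sel])
    cbind(groups[i, , drop = FALSE],
          data.frame(slope = f$slope, intercept = f$intercept,
                     r2 = f$r_squared, p = f$p_value, n = f$n))
  }))
  rownames(out) <- NULL
  out
}
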