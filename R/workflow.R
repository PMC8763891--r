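#' @title Whole-study convenience wrappers
#' @name workflow
NULL

#' Run the Bayesian decision analysis for every metal and zone
#'
#' Pairs the rows of a predicted (prior-source) and a field
#' (likelihood-source) statistics table by metal and zone, runs
#' [posterior_chart()] for each pair, and collects the results.
#'
#' @param predicted,field Stats tables with columns `metal`, `zone`, `n`,
#'   `gm`, `gsd` (see [read_exposure_stats()]).
#' @param scheme A [rating_scheme()]; must provide an OEL per metal.
#' @param encoding,statistic Passed to [posterior_chart()].
#' @param grid_fun Function `oel -> param_grid`; default [param_grid()]
#'   with its default bounds.
#' @return A list with `charts` (named list `metal_zone` of
#'   prior/likelihood/posterior triples) and `summary` (a data.frame with
#'   one row per metal/zone/role and columns `ER0`..`ER4`,
#'   `dominant_band`, `p_exceed_action`).
#' @export
run_bda_all <- function(predicted, field, scheme = rating_scheme(),
                        encoding = "suffstat", statistic = "x95",
                        grid_fun = param_grid) {
  charts <- list()
  rows <- list()
  for (i in seq_len(nrow(field))) {
    metal <- field$metal[i]; zone <- field$zone[i]
    prow <- predicted[predicted$metal == metal & predicted$zone == zone, ]
    if (nrow(prow) != 1) {
      stop("no unique predicted row for ", metal, "/", zone, call. = FALSE)
    }
    if (!metal %in% names(scheme$oels)) {
      stop("no OEL configured for metal ", metal, call. = FALSE)
    }
    oel <- scheme$oels[[metal]]
    grid <- grid_fun(oel)
    prior <- prior_from_dataset(as.list(prow[, c("gm", "gsd", "n")]), grid)
    trio <- posterior_chart(prior,
                            as.list(field[i, c("gm", "gsd", "n")]),
                            oel, scheme, encoding = encoding,
                            metal = metal, zone = zone,
                            statistic = statistic)
    charts[[paste(metal, zone, sep = "_")]] <- trio
    for (role in names(trio)) {
      ch <- trio[[role]]
      rows[[length(rows) + 1]] <- cbind(
        data.frame(metal = metal, zone = zone, role = role,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(ch$p)),
        data.frame(dominant_band = ch$dominant_band,
                   p_exceed_action = ch$p_exceed_action))
    }
  }
  list(charts = charts, summary = do.call(rbind, rows))
}

#' Prior-encoding sensitivity report
#'
#' Recomputes every posterior under both prior encodings (sufficient
#' statistic and category multiplication) and tabulates the band
#' probabilities side by side, flagging dominant-band disagreements.
#'
#' @inheritParams run_bda_all
#' @return A data.frame with one row per metal/zone/encoding and columns
#'   `ER0`..`ER4`, `dominant_band`.
#' @export
bda_sensitivity <- function(predicted, field, scheme = rating_scheme(),
                            statistic = "x95", grid_fun = param_grid) {
  out <- list()
  for (enc in c("suffstat", "category")) {
    res <- run_bda_all(predicted, field, scheme, encoding = enc,
                       statistic = statistic, grid_fun = grid_fun)
    s <- res$summary[res$summary$role == "posterior", ]
    s$encoding <- enc
    out[[enc]] <- s
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("metal", "zone", "encoding", paste0("ER", 0:4),
          "dominant_band", "p_exceed_action")]
}
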