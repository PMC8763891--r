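#' @title Table readers, writers and packaged study tables
#' @description CSV round-trip helpers for every table the pipeline
#'   consumes or emits, a YAML rating-scheme config reader, and accessors
#'   for the packaged study tables (chamber emission rates, simulation
#'   measurements, predicted long-term statistics, field statistics).
#'   CSV dialect: comma-separated, UTF-8, "." decimal, one header row.
#' @name io
NULL

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata` directory; omit to
#'   list the available files.
#' @return A file path (or a vector of file names).
#' @export
weldfume_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "weldfume"))
  } else {
    path <- system.file("extdata", file, package = "weldfume")
    if (path == "") stop("no packaged file '", file, "'", call. = FALSE)
    path
  }
}

#' Read/write an emission-rate table
#'
#' Columns: `metal`, `process`, `wire`, `current`, `er_mg_min`, `cv`, `n`.
#' The packaged `chamber_emission_rates.csv` carries the chamber-derived
#' rates per metal, process, wire and current (mg/min) with their
#' replicate CVs.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_emission_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metal", "process", "wire", "current", "er_mg_min")
  if (!all(req %in% names(x))) {
    stop("emission table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$er_mg_min < 0)) stop("negative emission rate", call. = FALSE)
  x
}

#' @rdname read_emission_table
#' @param x Data.frame to write.
#' @export
write_emission_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write paired zone concentrations
#'
#' Long format, one row per sample: `metal`, `process`, `wire`, `current`,
#' `zone` ("NF"/"FF"), `conc_mg_m3`. The packaged
#' `simulation_measured_concentrations.csv` holds the welding-simulation
#' measurements (60 NF/FF pairs: 5 metals x 3 currents x 4 wires).
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_concentration_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metal", "zone", "conc_mg_m3")
  if (!all(req %in% names(x))) {
    stop("concentration table must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(x$zone %in% c("NF", "FF"))) {
    stop("zone must be NF or FF", call. = FALSE)
  }
  x
}

#' @rdname read_concentration_table
#' @param x Data.frame to write.
#' @export
write_concentration_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Widen a paired concentration table into NF/FF columns
#'
#' @param x Long table as from [read_concentration_table()].
#' @return A data.frame with one row per metal/process/wire/current and
#'   columns `NF`, `FF`.
#' @export
pair_zones <- function(x) {
  key <- interaction(x$metal, x$process, x$wire, x$current, drop = TRUE)
  nf <- x[x$zone == "NF", ]
  ff <- x[x$zone == "FF", ]
  knf <- paste(nf$metal, nf$process, nf$wire, nf$current)
  kff <- paste(ff$metal, ff$process, ff$wire, ff$current)
  m <- match(knf, kff)
  if (anyNA(m)) stop("unpaired NF/FF rows", call. = FALSE)
  data.frame(metal = nf$metal, process = nf$process, wire = nf$wire,
             current = nf$current, NF = nf$conc_mg_m3,
             FF = ff$conc_mg_m3[m], stringsAsFactors = FALSE)
}

#' Read/write lognormal exposure statistics tables
#'
#' Columns: `metal`, `zone`, `n`, `gm`, `gsd`. Packaged instances:
#' `predicted_longterm_stats.csv` (model-predicted long-term GM/GSD per
#' metal and zone, n = 25 working days; the prior source) and
#' `field_exposure_stats.csv` (field personal/static sample GM/GSD,
#' n = 18; the likelihood source).
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_exposure_stats <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("metal", "zone", "n", "gm", "gsd")
  if (!all(req %in% names(x))) {
    stop("stats table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$gm <= 0) || any(x$gsd < 1)) {
    stop("need gm > 0 and gsd >= 1", call. = FALSE)
  }
  x
}

#' @rdname read_exposure_stats
#' @param x Data.frame to write.
#' @export
write_exposure_stats <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write operation-record tables
#'
#' Columns as produced by [gen_operation_records()].
#'
#' @param path CSV path.
#' @return A data.frame of operation records.
#' @export
read_operation_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("day_index", "process", "wire", "current", "Q", "beta",
           "V_N", "V_F", "duty_cycle")
  if (!all(req %in% names(x))) {
    stop("operation records must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(x$Q <= 0) || any(x$beta <= 0) || any(x$V_N <= 0) ||
      any(x$V_F <= 0)) {
    stop("flows and volumes must be strictly positive", call. = FALSE)
  }
  bad <- (startsWith(x$wire, "KFX") & x$process != "FCAW") |
    (startsWith(x$wire, "KM") & x$process != "GMAW")
  if (any(bad)) stop("inconsistent process/wire pairing", call. = FALSE)
  x
}

#' @rdname read_operation_records
#' @param x Data.frame to write.
#' @export
write_operation_records <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chamber trace CSV
#'
#' Two data columns (`time_min`, `conc_mg_m3`) preceded by a metadata
#' header block of `# key: value` lines carrying `volume`, `aer` and
#' optionally `k`, `p`, `c_out`.
#'
#' @param path CSV path.
#' @return A [chamber_series()].
#' @export
read_chamber_series <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(k = 0, p = 1, c_out = 0)
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":")[[1]]
    meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  if (is.null(meta$volume) || is.null(meta$aer)) {
    stop("chamber trace header must define volume and aer", call. = FALSE)
  }
  x <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  chamber_series(x$time_min, x$conc_mg_m3, meta$volume, meta$aer,
                 meta$k, meta$p, meta$c_out)
}

#' @rdname read_chamber_series
#' @param series A [chamber_series()] to write.
#' @export
write_chamber_series <- function(series, path) {
  stopifnot(inherits(series, "chamber_series"))
  hdr <- sprintf("# %s: %.15g",
                 c("volume", "aer", "k", "p", "c_out"),
                 c(series$volume, series$aer, series$k, series$p,
                   series$c_out[1]))
  writeLines(c(hdr, "time_min,conc_mg_m3",
               sprintf("%.15g,%.15g", series$times, series$c_in)), path)
  invisible(path)
}

#' Read a rating-scheme configuration
#'
#' YAML schema: `oels` (named map, mg/m3), optional `band_edges` (4
#' fractions of the OEL), optional `action_level_fraction` (must equal the
#' top band edge), optional `control_labels` (5 strings). Unknown keys are
#' rejected. The packaged `rating_scheme.yaml` holds the defaults.
#'
#' @param path YAML path.
#' @return A [rating_scheme()].
#' @export
read_rating_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("oels", "band_edges", "action_level_fraction",
             "control_labels")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown rating-scheme key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$oels)) stop("config must define oels", call. = FALSE)
  edges <- cfg$band_edges %||% c(0.005, 0.05, 0.25, 0.5)
  if (!is.null(cfg$action_level_fraction) &&
      cfg$action_level_fraction != edges[4]) {
    stop("action_level_fraction must equal the top band edge",
         call. = FALSE)
  }
  rating_scheme(unlist(cfg$oels), edges,
                cfg$control_labels %||% .wf_controls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write decision charts as JSON
#'
#' One JSON object per chart: metal, zone, role, the five band
#' probabilities, dominant band, action-level exceedance and recommended
#' control.
#'
#' @param charts A list of `decision_chart` objects.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_decision_charts <- function(charts, path) {
  if (inherits(charts, "decision_chart")) charts <- list(charts)
  payload <- lapply(charts, function(ch) {
    list(metal = ch$metal, zone = ch$zone, role = ch$role,
         oel_mg_m3 = ch$oel, p = as.list(ch$p),
         dominant_band = paste0("ER", ch$dominant_band),
         p_exceed_action = ch$p_exceed_action,
         recommended_control = ch$recommended_control)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
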