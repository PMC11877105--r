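#' Read cell tracks from CSV
#'
#' Expects one row per point with columns `track_id`, `frame`, `t_seconds`,
#' `x`, `y` (the layout produced by manual-tracking exports). Coordinates may
#' be in pixels; set `um_per_pixel` to convert — all downstream metrics are
#' in micrometres. Malformed tracks (duplicate frames, non-monotone times)
#' are reported by track id.
#'
#' @param path CSV file path.
#' @param um_per_pixel micrometres per pixel (default 1: coordinates already
#'   in um).
#' @param frame_interval_s nominal frame interval; default inferred from the
#'   median time gap.
#' @return A list of [track()] objects.
#' @export
read_tracks <- function(path, um_per_pixel = 1, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_seconds", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  out <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    if (anyDuplicated(d$frame))
      stop("duplicate frame index in track '", d$track_id[1], "'")
    fi <- if (is.null(frame_interval_s)) stats::median(diff(d$t_seconds))
          else frame_interval_s
    track(d$track_id[1], t = d$t_seconds,
          x = d$x * um_per_pixel, y = d$y * um_per_pixel,
          frame_interval = fi)
  })
  unname(out)
}

#' Write cell tracks to CSV
#'
#' Inverse of [read_tracks()] (with `um_per_pixel = 1`).
#'
#' @param tracks list of [track()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = seq_along(tr$t),
               t_seconds = tr$t, x = tr$x, y = tr$y,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read extracellular-flux series from CSV
#'
#' Expects columns `well_id`, `group`, `time_min` and at least one of
#' `ecar_mph_min`, `ocr_pmol_min`. The injection schedule comes from a
#' two-column CSV (`label`, `time_min`) or an [injection_schedule()] object,
#' and is validated against the assay's required injection order. Wells
#' whose rate columns are entirely empty are skipped with a warning.
#'
#' @param path flux CSV path.
#' @param injections an [injection_schedule()], or the path of a schedule
#'   CSV.
#' @param assay `"glycolysis"` or `"burst"` (sets the order invariant).
#' @return A list of [flux_series()] objects.
#' @export
read_flux <- function(path, injections, assay = c("glycolysis", "burst")) {
  assay <- match.arg(assay)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(injections)) {
    si <- utils::read.csv(injections, stringsAsFactors = FALSE)
    if (!all(c("label", "time_min") %in% names(si)))
      stop("injection schedule CSV needs columns label, time_min")
    injections <- injection_schedule(si$label, si$time_min, assay = assay)
  }
  if (!inherits(injections, "injection_schedule"))
    stop("injections must be an injection_schedule or a CSV path")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "group", "time_min")
  if (length(setdiff(need, names(df))))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  has_ecar <- "ecar_mph_min" %in% names(df)
  has_ocr <- "ocr_pmol_min" %in% names(df)
  if (!has_ecar && !has_ocr)
    stop("flux CSV needs ecar_mph_min and/or ocr_pmol_min")
  out <- list()
  for (d in split(df, df$well_id)) {
    d <- d[order(d$time_min), ]
    ecar <- if (has_ecar && !all(is.na(d$ecar_mph_min))) d$ecar_mph_min
    ocr <- if (has_ocr && !all(is.na(d$ocr_pmol_min))) d$ocr_pmol_min
    if (is.null(ecar) && is.null(ocr)) {
      warning("well '", d$well_id[1], "' has no rate data; skipped")
      next
    }
    out[[length(out) + 1L]] <- flux_series(
      d$well_id[1], d$time_min, ecar = ecar, ocr = ocr,
      injections = injections, group = d$group[1])
  }
  out
}

#' Read a subject-level cohort table from CSV
#'
#' Expects `subject_id`, `group`, then one column per variable. Character
#' columns are treated as categorical, numeric columns as continuous;
#' missing values stay `NA` (they are excluded pairwise at analysis time).
#'
#' @param path cohort CSV path.
#' @param groups optional declared group set; labels outside it are an
#'   error.
#' @return A data.frame.
#' @export
read_cohort <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("subject_id", "group"), names(df))))
    stop("cohort CSV needs subject_id and group columns")
  if (!is.null(groups)) {
    bad <- setdiff(unique(df$group), groups)
    if (length(bad))
      stop("undeclared group label(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Write a JSON provenance sidecar for a simulation
#'
#' Records generator parameters and seed next to a simulated data file so
#' any output can be regenerated byte-for-byte.
#'
#' @param path path of the data file the sidecar describes; the sidecar is
#'   written at `<path>.json`.
#' @param params named list of generator parameters.
#' @param seed the root seed used.
#' @return The sidecar path, invisibly.
#' @export
write_provenance <- function(path, params, seed) {
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(generator = "neutrofun", seed = seed, params = params,
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Default run configuration
#'
#' All tunables of the pipeline with their documented defaults: gradient
#' direction, PER constants, QC tolerance, normality-gate alpha, t-test
#' flavour, sample-size rounding, minimum track steps and pixel scale.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    gradient_x = 0, gradient_y = 1,
    um_per_pixel = 1,
    min_track_steps = 10,
    buffer_factor = 2.6, chamber_volume = 2.28, kvol = 1.6,
    qc_tol = 0.15,
    normality_alpha = 0.05,
    t_test = "student",       # or "welch"
    rounding = "nearest",     # or "ceiling"
    fold_method = "peak"      # or "mean"
  )
}

#' Read a YAML run configuration
#'
#' Keys absent from the file keep their [default_config()] values; unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
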