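#' Injection schedule for an extracellular-flux assay
#'
#' The glycolysis assay injects PMA after the baseline measurements, then
#' oligomycin (to confirm acidification is glycolytic, not mitochondrial),
#' then 2-deoxyglucose (to confirm full shutdown). The oxidative-burst assay
#' pre-treats with rotenone/antimycin A and then injects PMA.
#'
#' @param labels character vector drawn from `PMA`, `oligomycin`, `2DG`,
#'   `RotAA`; unique.
#' @param times_min injection times in minutes, strictly increasing, >= 0.
#' @param assay `"glycolysis"` enforces PMA < oligomycin < 2DG;
#'   `"burst"` enforces RotAA < PMA; `"none"` skips the order check.
#' @return A data.frame with columns `label`, `time_min`, class
#'   `"injection_schedule"`.
#' @export
injection_schedule <- function(labels, times_min,
                               assay = c("glycolysis", "burst", "none")) {
  assay <- match.arg(assay)
  labels <- as.character(labels)
  times_min <- as.numeric(times_min)
  if (length(labels) != length(times_min))
    stop("labels and times_min must have equal length")
  allowed <- c("PMA", "oligomycin", "2DG", "RotAA")
  if (!all(labels %in% allowed))
    stop("unknown injection label(s): ",
         paste(setdiff(labels, allowed), collapse = ", "))
  if (anyDuplicated(labels)) stop("injection labels must be unique")
  if (any(times_min < 0) || any(diff(times_min) <= 0))
    stop("injection times must be nonnegative and strictly increasing")
  inj_time <- function(lab) times_min[match(lab, labels)]
  if (assay == "glycolysis") {
    need <- c("PMA", "oligomycin", "2DG")
    if (!all(need %in% labels))
      stop("glycolysis assay requires PMA, oligomycin and 2DG injections")
    if (!(inj_time("PMA") < inj_time("oligomycin") &&
          inj_time("oligomycin") < inj_time("2DG")))
      stop("glycolysis assay requires PMA < oligomycin < 2DG")
  } else if (assay == "burst") {
    if (!("PMA" %in% labels)) stop("burst assay requires a PMA injection")
    if ("RotAA" %in% labels && !(inj_time("RotAA") < inj_time("PMA")))
      stop("burst assay requires RotAA before PMA")
  }
  structure(data.frame(label = labels, time_min = times_min,
                       stringsAsFactors = FALSE),
            class = c("injection_schedule", "data.frame"))
}

injection_time <- function(schedule, label) {
  i <- match(label, schedule$label)
  if (is.na(i)) stop("no ", label, " injection in schedule")
  schedule$time_min[i]
}

#' Per-well extracellular-flux time series
#'
#' @param well_id well label.
#' @param time_min measurement times in minutes, strictly increasing.
#' @param ecar extracellular acidification rate (mpH/min) per timepoint, or
#'   `NULL` for a burst (OCR-only) series.
#' @param ocr oxygen consumption rate (pmol O2/min) per timepoint, or `NULL`.
#' @param injections an [injection_schedule()].
#' @param group optional group label (e.g. `"CAP"`, `"control"`).
#' @return An object of class `"flux_series"`.
#' @export
flux_series <- function(well_id, time_min, ecar = NULL, ocr = NULL,
                        injections, group = NA_character_) {
  time_min <- as.numeric(time_min)
  if (length(time_min) < 2L || any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing with >= 2 points")
  for (nm in c("ecar", "ocr")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != length(time_min))
      stop(nm, " length must match time_min")
  }
  if (is.null(ecar) && is.null(ocr))
    stop("flux series needs at least one of ecar, ocr")
  if (!inherits(injections, "injection_schedule"))
    stop("injections must be an injection_schedule")
  stim <- injections$time_min[injections$label == "PMA"]
  if (length(stim) == 1L && sum(time_min < stim) < 2L)
    stop("well '", well_id, "': fewer than 2 measurements before PMA")
  structure(
    list(well_id = as.character(well_id), group = as.character(group),
         time_min = time_min,
         ecar = if (is.null(ecar)) NULL else as.numeric(ecar),
         ocr = if (is.null(ocr)) NULL else as.numeric(ocr),
         injections = injections),
    class = "flux_series"
  )
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series %s (%s): %d timepoints, %s; injections: %s>\n",
              x$well_id, x$group, length(x$time_min),
              paste(c("ECAR", "OCR")[c(!is.null(x$ecar), !is.null(x$ocr))],
                    collapse = "+"),
              paste(sprintf("%s@%g", x$injections$label,
                            x$injections$time_min), collapse = ", ")))
  invisible(x)
}

#' Proton-efflux-rate conversion constants
#'
#' ECAR (mpH/min) is converted to proton efflux rate (pmol H+/min) to account
#' for the buffering capacity of the assay medium:
#' `PER = ECAR x buffer_factor x chamber_volume x kvol`
#' (mpH/min x mmol H+/L/pH x uL -> pmol H+/min). Defaults are the standard
#' instrument constants for the glycolytic-rate assay medium; override for
#' other media.
#'
#' @param buffer_factor medium buffering capacity, mmol H+/L/pH (> 0).
#' @param chamber_volume measurement chamber volume, uL (> 0).
#' @param kvol dimensionless volume scaling constant (> 0).
#' @return A list of class `"per_params"`.
#' @export
per_params <- function(buffer_factor = 2.6, chamber_volume = 2.28,
                       kvol = 1.6) {
  vals <- c(buffer_factor, chamber_volume, kvol)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all PER parameters must be strictly positive")
  structure(list(buffer_factor = buffer_factor,
                 chamber_volume = chamber_volume, kvol = kvol),
            class = "per_params")
}

#' Convert ECAR to proton efflux rate
#'
#' @param ecar ECAR value(s), mpH/min. Negative values are passed through
#'   (they are QC-flagged downstream, never clipped).
#' @param params a [per_params()] object.
#' @return PER in pmol H+/min, same length as `ecar`.
#' @examples
#' ecar_to_per(20, per_params(2.6, 2.28, 1.6))  # 189.696
#' @export
ecar_to_per <- function(ecar, params = per_params()) {
  stopifnot(inherits(params, "per_params"))
  as.numeric(ecar) * params$buffer_factor * params$chamber_volume *
    params$kvol
}

per_trace <- function(series, params) {
  if (is.null(series$ecar)) stop("series has no ECAR trace")
  ecar_to_per(series$ecar, params)
}

#' Basal glycolysis of a flux series
#'
#' Basal glycolysis is the PER of the last measurement strictly before the
#' PMA injection — a single measurement, not a mean over the baseline window.
#'
#' @param series a [flux_series()] with an ECAR trace and a PMA injection.
#' @param params a [per_params()].
#' @return Basal PER in pmol H+/min.
#' @export
basal_glycolysis <- function(series, params = per_params()) {
  stopifnot(inherits(series, "flux_series"))
  pma <- injection_time(series$injections, "PMA")
  pre <- which(series$time_min < pma)
  if (length(pre) == 0L) stop("no measurement before PMA injection")
  per_trace(series, params)[max(pre)]
}

#' Fold change in glycolysis after PMA
#'
#' PER response to PMA relative to basal: the maximum (default) or mean PER
#' in the window after the PMA injection and before oligomycin, divided by
#' [basal_glycolysis()]. Measurements after oligomycin are never counted —
#' oligomycin perturbs the signal by design.
#'
#' @inheritParams basal_glycolysis
#' @param method `"peak"` (default) or `"mean"` summary of the post-PMA
#'   window.
#' @return Dimensionless fold change (> 0 for a responding well), or `NA`
#'   with a warning when basal PER is not positive.
#' @export
fold_change_glycolysis <- function(series, params = per_params(),
                                   method = c("peak", "mean")) {
  method <- match.arg(method)
  basal <- basal_glycolysis(series, params)
  pma <- injection_time(series$injections, "PMA")
  oligo <- injection_time(series$injections, "oligomycin")
  win <- series$time_min > pma & series$time_min < oligo
  if (!any(win)) stop("no measurement between PMA and oligomycin")
  if (basal <= 0) {
    warning("fold change undefined: basal PER <= 0")
    return(NA_real_)
  }
  per <- per_trace(series, params)[win]
  if (method == "peak") max(per) / basal else mean(per) / basal
}

#' QC annotation of a glycolysis flux series
#'
#' Checks the two internal controls of the glycolytic-rate assay: after
#' oligomycin the PER should barely move from the level attained just before
#' it (a drop means part of the measured acidification was mitochondrial),
#' and after 2-deoxyglucose the PER should collapse (residual activity means
#' glycolysis was not fully inhibited). Negative measured rates are also
#' flagged. Pure annotation: no value is modified.
#'
#' @inheritParams basal_glycolysis
#' @param tol tolerated fractional change after oligomycin, and tolerated
#'   post-2DG PER as a fraction of basal. Default 0.15.
#' @return A one-row data.frame: `well_id`, `oligo_sensitive`,
#'   `incomplete_2dg_inhibition`, `negative_rates`, plus the measured
#'   fractions behind the flags.
#' @export
qc_flags <- function(series, params = per_params(), tol = 0.15) {
  stopifnot(inherits(series, "flux_series"))
  per <- per_trace(series, params)
  tm <- series$time_min
  pma <- injection_time(series$injections, "PMA")
  oligo <- injection_time(series$injections, "oligomycin")
  dg <- injection_time(series$injections, "2DG")
  basal <- basal_glycolysis(series, params)
  pre_oligo <- per[tm > pma & tm < oligo]
  post_oligo <- per[tm > oligo & tm < dg]
  post_dg <- per[tm > dg]
  # reference level: last measurement before oligomycin (the attained
  # stimulated plateau), not the mean of the still-rising PMA window
  oligo_change <- if (length(pre_oligo) && length(post_oligo) &&
                      pre_oligo[length(pre_oligo)] != 0) {
    ref <- pre_oligo[length(pre_oligo)]
    (mean(post_oligo) - ref) / abs(ref)
  } else NA_real_
  resid_2dg <- if (length(post_dg) && basal > 0) {
    mean(post_dg) / basal
  } else NA_real_
  data.frame(
    well_id = series$well_id,
    oligo_sensitive = isTRUE(abs(oligo_change) > tol),
    incomplete_2dg_inhibition = isTRUE(resid_2dg > tol),
    negative_rates = any(per < 0),
    oligo_change = oligo_change,
    residual_after_2dg = resid_2dg,
    stringsAsFactors = FALSE
  )
}

#' Glycolysis summary of one well
#'
#' Convenience wrapper returning basal PER, fold change and the QC record in
#' one row.
#'
#' @inheritParams fold_change_glycolysis
#' @param tol QC tolerance, as in [qc_flags()].
#' @return One-row data.frame: `well_id`, `group`, `basal_per`,
#'   `fold_change`, `oligo_change`, `residual_after_2dg`, QC flags.
#' @export
glycolysis_summary <- function(series, params = per_params(),
                               method = "peak", tol = 0.15) {
  qc <- qc_flags(series, params, tol)
  data.frame(
    well_id = series$well_id, group = series$group,
    basal_per = basal_glycolysis(series, params),
    fold_change = fold_change_glycolysis(series, params, method),
    oligo_change = qc$oligo_change,
    residual_after_2dg = qc$residual_after_2dg,
    oligo_sensitive = qc$oligo_sensitive,
    incomplete_2dg_inhibition = qc$incomplete_2dg_inhibition,
    negative_rates = qc$negative_rates,
    stringsAsFactors = FALSE
  )
}

#' Oxidative-burst kinetics of an OCR series
#'
#' Summarises the respiratory burst from the post-PMA OCR curve: total oxygen
#' consumption as the trapezoidal area under the curve from the PMA injection
#' to the last timepoint, peak OCR, and time to peak. Time to peak is
#' reported relative to the PMA injection by default; `time_ref =
#' "absolute"` reports it on the assay clock instead.
#'
#' @param series a [flux_series()] with an OCR trace and a PMA injection.
#' @param time_ref `"pma"` (default, minutes since PMA) or `"absolute"`.
#' @param baseline_subtract subtract the mean pre-PMA OCR before
#'   integrating. Off by default: rotenone/antimycin A already suppress
#'   mitochondrial oxygen uptake in this assay.
#' @return One-row data.frame: `well_id`, `group`, `total_o2` (pmol),
#'   `peak_ocr` (pmol/min), `time_to_peak` (min), `peak_right_censored`
#'   (TRUE when the maximum sits on the final timepoint, so the true peak may
#'   lie beyond the assay).
#' @export
burst_summary <- function(series, time_ref = c("pma", "absolute"),
                          baseline_subtract = FALSE) {
  time_ref <- match.arg(time_ref)
  stopifnot(inherits(series, "flux_series"))
  if (is.null(series$ocr)) stop("series has no OCR trace")
  pma <- injection_time(series$injections, "PMA")
  post <- series$time_min >= pma
  if (sum(post) < 2L) stop("fewer than 2 post-PMA measurements")
  tm <- series$time_min[post]
  ocr <- series$ocr[post]
  if (baseline_subtract) {
    base <- mean(series$ocr[series$time_min < pma])
    ocr <- ocr - base
  }
  i_peak <- which.max(ocr)
  data.frame(
    well_id = series$well_id, group = series$group,
    total_o2 = pracma::trapz(tm, ocr),
    peak_ocr = ocr[i_peak],
    time_to_peak = if (time_ref == "pma") tm[i_peak] - pma else tm[i_peak],
    peak_right_censored = i_peak == length(ocr),
    stringsAsFactors = FALSE
  )
}
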