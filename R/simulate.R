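#' Derive a per-component substream seed from a root seed
#'
#' One root seed expands to independent per-component seeds by hashing the
#' component name, so adding a generator never perturbs the streams of
#' existing ones. The result is kept below 2^31 for use with [set.seed()].
#'
#' @param seed root integer seed.
#' @param component component name, e.g. `"tracks"`.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 69069 + h * 30011) %% 2147483647)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler for circular directions with mean `mu` and
#' concentration `kappa`; `kappa = 0` gives the uniform circle. The mean
#' resultant length (hence the expected chemotactic index of steps drawn
#' toward the gradient) is the Bessel ratio I1(kappa)/I0(kappa).
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return Angles in radians in (-pi, pi\].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  # Best & Fisher (1979) wrapped-Cauchy envelope rejection
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      theta <- mu + sign(u3 - 0.5) * acos(f)
      out[i] <- atan2(sin(theta), cos(theta))
      i <- i + 1L
    }
  }
  out
}

#' Simulate chemotaxing cell tracks as biased random walks
#'
#' Each cell starts at the origin and takes `n_frames - 1` steps: step
#' direction drawn from a von Mises distribution centred on the gradient
#' direction with concentration `kappa` (kappa = 0 is an unbiased walk, the
#' negative-control chamber), step length drawn from a gamma distribution.
#' The defaults reproduce the migration-assay protocol: 37 frames at 20 s,
#' i.e. a 12 min time-lapse per cell. The ensemble-mean chemotactic index of
#' such walks is I1(kappa)/I0(kappa).
#'
#' @param n_cells number of cells.
#' @param n_frames frames per track (default 37).
#' @param frame_interval_s seconds between frames (default 20).
#' @param kappa von Mises concentration toward the gradient (>= 0).
#' @param step_mean_um mean step length, um.
#' @param step_shape gamma shape of the step-length distribution.
#' @param gradient gradient direction, as in [chemotactic_index()].
#' @param seed integer seed; same seed, same tracks.
#' @return A list of [track()] objects.
#' @export
simulate_tracks <- function(n_cells, n_frames = 37, frame_interval_s = 20,
                            kappa = 1, step_mean_um = 1, step_shape = 2,
                            gradient = gradient_spec(), seed = 1) {
  stopifnot(n_cells >= 1, n_frames >= 2, frame_interval_s > 0,
            kappa >= 0, step_mean_um > 0, step_shape > 0)
  g <- as_gradient(gradient)
  mu <- atan2(g[2], g[1])
  set.seed(substream_seed(seed, "tracks"))
  t <- (seq_len(n_frames) - 1) * frame_interval_s
  lapply(seq_len(n_cells), function(i) {
    ang <- rvonmises(n_frames - 1L, mu = mu, kappa = kappa)
    len <- stats::rgamma(n_frames - 1L, shape = step_shape,
                         scale = step_mean_um / step_shape)
    track(sprintf("cell_%03d", i), t = t,
          x = c(0, cumsum(len * cos(ang))),
          y = c(0, cumsum(len * sin(ang))),
          frame_interval = frame_interval_s)
  })
}

#' Simulate tracks for several subjects with heterogeneous bias
#'
#' Hierarchical version of [simulate_tracks()]: each subject's von Mises
#' concentration is drawn from a gamma hyperprior with mean `kappa_mean` and
#' coefficient of variation `kappa_cv`, so per-subject chemotactic indices
#' show realistic between-donor spread instead of all sitting at one value.
#'
#' @param n_subjects number of subjects.
#' @param n_cells cells tracked per subject.
#' @param kappa_mean mean concentration across subjects.
#' @param kappa_cv coefficient of variation of the concentration
#'   hyperprior (default 0.3).
#' @inheritParams simulate_tracks
#' @return A named list, one entry per subject, each a list of tracks; the
#'   drawn `kappa` is attached as an attribute of each entry.
#' @export
simulate_track_subjects <- function(n_subjects, n_cells = 30,
                                    kappa_mean = 1, kappa_cv = 0.3,
                                    gradient = gradient_spec(), seed = 1,
                                    ...) {
  set.seed(substream_seed(seed, "track_subjects"))
  shape <- 1 / kappa_cv^2
  kappas <- if (kappa_mean == 0) rep(0, n_subjects) else
    stats::rgamma(n_subjects, shape = shape, scale = kappa_mean / shape)
  out <- lapply(seq_len(n_subjects), function(s) {
    trs <- simulate_tracks(n_cells, kappa = kappas[s], gradient = gradient,
                           seed = substream_seed(seed, paste0("subj", s)),
                           ...)
    attr(trs, "kappa") <- kappas[s]
    trs
  })
  names(out) <- sprintf("subject_%02d", seq_len(n_subjects))
  out
}

#' Simulate a glycolysis extracellular-flux series
#'
#' Piecewise PER curve mimicking the glycolytic-rate assay: a basal plateau
#' up to the PMA injection; a saturating rise after PMA, normalised so the
#' last pre-oligomycin measurement sits exactly at `basal_per * fold` (which
#' makes noise-free recovery of `fold` by [fold_change_glycolysis()] exact);
#' removal of an optional mitochondrial component after oligomycin; and
#' exponential collapse after 2-deoxyglucose. Gaussian measurement noise is
#' added on the PER scale, then the trace is stored as ECAR via the inverse
#' of [ecar_to_per()].
#'
#' @param basal_per basal glycolytic PER, pmol H+/min.
#' @param fold fold change at the post-PMA peak (>= 1).
#' @param rise_rate rate constant of the post-PMA rise, 1/min.
#' @param pma_time,oligo_time,dg_time injection times, min
#'   (PMA < oligomycin < 2DG).
#' @param duration assay length, min.
#' @param dt measurement spacing, min.
#' @param noise_sd SD of additive Gaussian noise on PER, pmol H+/min.
#' @param mito_fraction mitochondrial acidification as a fraction of the
#'   glycolytic signal, removed after oligomycin; 0 (default) gives a
#'   QC-clean well, larger values trip the oligomycin flag. Nonzero values
#'   inflate the measured basal too, exactly as real mitochondrial
#'   acidification would (that is what the oligomycin control detects).
#' @param params [per_params()] used to store the trace as ECAR.
#' @param well_id,group labels.
#' @param seed integer seed.
#' @return A [flux_series()] with an ECAR trace and the glycolysis schedule.
#' @export
simulate_flux <- function(basal_per = 114, fold = 3.4, rise_rate = 0.1,
                          pma_time = 18, oligo_time = 54, dg_time = 78,
                          duration = 96, dt = 6, noise_sd = 0,
                          mito_fraction = 0, params = per_params(),
                          well_id = "A1", group = NA_character_, seed = 1) {
  stopifnot(pma_time < oligo_time, oligo_time < dg_time, fold >= 1,
            noise_sd >= 0, mito_fraction >= 0, basal_per > 0)
  set.seed(substream_seed(seed, paste0("flux_", well_id)))
  tm <- seq(dt / 2, duration, by = dt)  # measurements between injections
  win <- tm[tm > pma_time & tm < oligo_time]
  if (length(win) == 0L) stop("no measurement between PMA and oligomycin")
  t_top <- max(win)
  rise <- function(t) (1 - exp(-rise_rate * (t - pma_time))) /
    (1 - exp(-rise_rate * (t_top - pma_time)))
  glyco <- ifelse(tm <= pma_time, basal_per,
           ifelse(tm < oligo_time, basal_per + basal_per * (fold - 1) * rise(tm),
           ifelse(tm < dg_time, basal_per * fold,
                  basal_per * fold * exp(-0.8 * (tm - dg_time)))))
  mito <- ifelse(tm < oligo_time, mito_fraction * glyco, 0)
  per <- glyco + mito + stats::rnorm(length(tm), 0, noise_sd)
  ecar <- per / (params$buffer_factor * params$chamber_volume * params$kvol)
  flux_series(well_id, tm, ecar = ecar,
              injections = injection_schedule(
                c("PMA", "oligomycin", "2DG"),
                c(pma_time, oligo_time, dg_time), assay = "glycolysis"),
              group = group)
}

#' Closed-form area of the simulated burst pulse
#'
#' The burst generator uses the gamma-shaped pulse
#' `peak * (s/m)^a * exp(a (1 - s/m))` with `s` minutes after PMA, mode
#' `m = t_peak` and `a = (t_peak/width)^2`; its integral over s in (0, Inf)
#' is `peak * m * exp(a + lgamma(a+1) - (a+1) log(a))`. Used as the analytic
#' reference for the trapezoidal AUC.
#'
#' @param peak pulse peak, pmol/min.
#' @param t_peak mode, minutes after PMA.
#' @param width width parameter, min.
#' @return Area in pmol.
#' @export
burst_pulse_area <- function(peak, t_peak, width) {
  a <- (t_peak / width)^2
  peak * t_peak * exp(a + lgamma(a + 1) - (a + 1) * log(a))
}

#' Simulate an oxidative-burst OCR series
#'
#' OCR is near zero before PMA (rotenone/antimycin A suppress mitochondrial
#' respiration), then follows a single gamma-shaped pulse peaking `t_peak`
#' minutes after the injection, plus optional Gaussian noise.
#'
#' @param peak peak OCR, pmol O2/min.
#' @param t_peak minutes after PMA at which OCR peaks.
#' @param width pulse width parameter, min (larger = broader burst).
#' @param pma_time PMA injection time, min.
#' @param duration assay length, min.
#' @param dt measurement spacing, min.
#' @param noise_sd SD of additive Gaussian noise, pmol/min.
#' @param well_id,group labels.
#' @param seed integer seed.
#' @return A [flux_series()] with an OCR trace, RotAA at 0 and PMA at
#'   `pma_time`.
#' @export
simulate_burst <- function(peak = 200, t_peak = 90, width = 40,
                           pma_time = 12, duration = 200, dt = 6,
                           noise_sd = 0, well_id = "A1",
                           group = NA_character_, seed = 1) {
  stopifnot(t_peak > 0, t_peak < duration - pma_time, width > 0,
            noise_sd >= 0)
  set.seed(substream_seed(seed, paste0("burst_", well_id)))
  tm <- seq(dt / 2, duration, by = dt)
  s <- pmax(tm - pma_time, 0)
  a <- (t_peak / width)^2
  ocr <- ifelse(s > 0, peak * (s / t_peak)^a * exp(a * (1 - s / t_peak)), 0)
  ocr <- ocr + stats::rnorm(length(tm), 0, noise_sd)
  flux_series(well_id, tm, ocr = ocr,
              injections = injection_schedule(
                c("RotAA", "PMA"), c(min(tm[1] / 2, pma_time / 2), pma_time),
                assay = "burst"),
              group = group)
}

#' Simulate a two-group subject-level cohort table
#'
#' Draws each variable independently per subject from its group-specific
#' generating distribution. Continuous variables are `normal` (mean, sd) or
#' `lognormal` parameterised by the printed median and IQR (meanlog from the
#' median, sdlog from the IQR ratio — the natural way to match a reported
#' median (IQR) summary); `categorical` variables take per-group level
#' probabilities.
#'
#' @param n_per_group named integer vector, e.g.
#'   `c(control = 23, CAP = 14)`.
#' @param variables named list; each element is a list with `type`
#'   (`"normal"`, `"lognormal"`, `"categorical"`) and per-group parameters:
#'   for `normal`, `mean` and `sd` (named by group); for `lognormal`,
#'   `median` and `iqr` (each a named list of `c(q1, q3)` or a scalar
#'   median); for `categorical`, `prob` (named list of named probability
#'   vectors summing to 1).
#' @param seed integer seed.
#' @return A data.frame: `subject_id`, `group`, one column per variable.
#' @examples
#' cohort <- simulate_cohort(
#'   c(control = 23, CAP = 14),
#'   list(chemotactic_index = list(
#'     type = "normal",
#'     mean = c(control = 0.31, CAP = 0.14),
#'     sd = c(control = 0.13, CAP = 0.03))),
#'   seed = 1)
#' head(cohort)
#' @export
simulate_cohort <- function(n_per_group, variables, seed = 1) {
  stopifnot(length(n_per_group) >= 1, !is.null(names(n_per_group)),
            all(n_per_group >= 1))
  set.seed(substream_seed(seed, "cohort"))
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups, stringsAsFactors = FALSE)
  for (v in names(variables)) {
    spec <- variables[[v]]
    col <- rep(NA, n)
    for (g in names(n_per_group)) {
      idx <- which(groups == g)
      col[idx] <- switch(
        spec$type,
        normal = stats::rnorm(length(idx), spec$mean[[g]], spec$sd[[g]]),
        lognormal = {
          q <- spec$iqr[[g]]
          sdlog <- log(q[2] / q[1]) / (2 * stats::qnorm(0.75))
          stats::rlnorm(length(idx), meanlog = log(spec$median[[g]]),
                        sdlog = sdlog)
        },
        categorical = {
          p <- spec$prob[[g]]
          sample(names(p), length(idx), replace = TRUE, prob = p)
        },
        stop("unknown variable type '", spec$type, "' for ", v))
    }
    out[[v]] <- if (spec$type == "categorical") as.character(col)
                else as.numeric(col)
  }
  out
}

#' Simulate AnV/PI cytometry events with known quadrant probabilities
#'
#' @param n number of events.
#' @param probs length-4 probability vector for (viable, early apoptotic,
#'   late apoptotic, necrotic); must sum to 1.
#' @param seed integer seed.
#' @return A data.frame with logical columns `anv`, `pi`.
#' @export
simulate_viability_events <- function(n, probs = c(0.6, 0.2, 0.15, 0.05),
                                      seed = 1) {
  stopifnot(length(probs) == 4, abs(sum(probs) - 1) < 1e-8, n >= 1)
  set.seed(substream_seed(seed, "viability"))
  state <- sample.int(4, n, replace = TRUE, prob = probs)
  data.frame(anv = state %in% c(2L, 3L), pi = state %in% c(3L, 4L))
}

#' Simulate single-marker cytometry fluorescence with an isotype control
#'
#' Two lognormal populations (negative at the isotype level, positive well
#' above it) mixed at `pos_fraction`, plus a matched isotype sample, for
#' testing isotype-gated percent-positive estimation.
#'
#' @param n stained events; `n_isotype` isotype events.
#' @param pos_fraction true positive fraction.
#' @param neg_meanlog,pos_meanlog,sdlog lognormal parameters of the two
#'   populations (isotype events share the negative population).
#' @param n_isotype number of isotype-control events.
#' @param seed integer seed.
#' @return A list: `events`, `isotype_events`, `is_positive` (truth).
#' @export
simulate_marker_events <- function(n, pos_fraction = 0.68,
                                   neg_meanlog = log(100),
                                   pos_meanlog = log(5000), sdlog = 0.35,
                                   n_isotype = 2000, seed = 1) {
  stopifnot(pos_fraction >= 0, pos_fraction <= 1, n >= 1)
  set.seed(substream_seed(seed, "marker"))
  pos <- stats::runif(n) < pos_fraction
  events <- stats::rlnorm(n, ifelse(pos, pos_meanlog, neg_meanlog), sdlog)
  iso <- stats::rlnorm(n_isotype, neg_meanlog, sdlog)
  list(events = events, isotype_events = iso, is_positive = pos)
}
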