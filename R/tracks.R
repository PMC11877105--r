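#' Construct a cell track
#'
#' A track is one cell's time-ordered 2-D path from time-lapse microscopy,
#' sampled at a nominally fixed frame interval (the migration assay captures
#' an image every 20 s for 12 min, i.e. 37 frames). Coordinates are in
#' micrometres; apply any pixel scale before construction (see
#' [read_tracks()]).
#'
#' @param track_id opaque cell label.
#' @param t time of each point in seconds, strictly increasing.
#' @param x,y coordinates in micrometres, same length as `t`, all finite.
#' @param frame_interval nominal frame interval in seconds (> 0). Consecutive
#'   time gaps must equal it within `tol`.
#' @param tol relative tolerance on the frame-interval check.
#' @return An object of class `"track"`: a list with fields `track_id`,
#'   `frame_interval`, `t`, `x`, `y`.
#' @examples
#' tr <- track("cell1", t = c(0, 20, 40), x = c(0, 1, 2), y = c(0, 0, 0))
#' step_vectors(tr)
#' @export
track <- function(track_id, t, x, y, frame_interval = 20, tol = 1e-6) {
  if (length(t) < 2L)
    stop("malformed track '", track_id, "': needs at least 2 points")
  if (length(x) != length(t) || length(y) != length(t))
    stop("malformed track '", track_id, "': t, x, y lengths differ")
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("malformed track '", track_id, "': non-finite values")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("malformed track '", track_id, "': times not strictly increasing")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (any(abs(dt - frame_interval) > tol * frame_interval + 1e-9))
    stop("malformed track '", track_id,
         "': frame gaps deviate from frame_interval")
  structure(
    list(track_id = as.character(track_id),
         frame_interval = frame_interval,
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
    class = "track"
  )
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s: %d points, %.0f s interval, %.1f min span>\n",
              x$track_id, length(x$t), x$frame_interval,
              (x$t[length(x$t)] - x$t[1]) / 60))
  invisible(x)
}

#' Chemoattractant gradient direction
#'
#' Unit vector pointing toward the chemoattractant source. The default
#' convention is "up" in image coordinates, `(0, 1)`, i.e. toward the
#' chemoattractant well of the chamber; the imaging orientation is
#' configurable because tracking exports do not record it.
#'
#' @param x,y components of the direction; need not be normalised.
#' @return A unit-norm numeric vector of length 2 with class
#'   `"gradient_spec"`.
#' @examples
#' gradient_spec(0, 1)   # toward the top of the image
#' @export
gradient_spec <- function(x = 0, y = 1) {
  v <- c(as.numeric(x), as.numeric(y))
  if (!all(is.finite(v))) stop("gradient direction must be finite")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("gradient direction must be nonzero")
  structure(v / n, class = "gradient_spec")
}

as_gradient <- function(g) {
  if (inherits(g, "gradient_spec")) return(unclass(g))
  if (is.numeric(g) && length(g) == 2L) return(unclass(gradient_spec(g[1], g[2])))
  stop("gradient must be a gradient_spec or a length-2 numeric vector")
}

#' Per-frame displacement vectors of a track
#'
#' @param track a [track()] object.
#' @return A matrix with one row per step (n_points - 1 rows) and columns
#'   `dx`, `dy`, in micrometres.
#' @export
step_vectors <- function(track) {
  stopifnot(inherits(track, "track"))
  cbind(dx = diff(track$x), dy = diff(track$y))
}

#' Chemotactic index of a track
#'
#' Per-frame directional accuracy toward the chemoattractant: the mean over
#' steps of the cosine of the angle between each step vector and the gradient
#' direction. 1 means every step is directly toward the source, -1 directly
#' away. Zero-length steps have no direction and are excluded; their count is
#' available from [track_metrics()].
#'
#' @inheritParams step_vectors
#' @param gradient a [gradient_spec()] (or length-2 numeric) toward the
#'   chemoattractant.
#' @return Chemotactic index in \[-1, 1\], or `NA` (with a warning) if every
#'   step has zero length.
#' @export
chemotactic_index <- function(track, gradient = gradient_spec()) {
  g <- as_gradient(gradient)
  sv <- step_vectors(track)
  len <- sqrt(rowSums(sv^2))
  keep <- len > 0
  if (!any(keep)) {
    warning("chemotactic index undefined: all steps have zero length")
    return(NA_real_)
  }
  cosines <- (sv[keep, 1] * g[1] + sv[keep, 2] * g[2]) / len[keep]
  # numerical guard: |cos| can exceed 1 by rounding
  mean(pmin(1, pmax(-1, cosines)))
}

#' Directness of a track
#'
#' Straightness of travel over the whole time-lapse: net displacement
#' (straight-line distance between start and end point, irrespective of
#' direction) divided by the total distance travelled. 1 is a perfectly
#' straight path.
#'
#' @inheritParams step_vectors
#' @return Directness in \[0, 1\], or `NA` (with a warning) for a track with
#'   zero total path length.
#' @export
directness <- function(track) {
  sv <- step_vectors(track)
  total <- sum(sqrt(rowSums(sv^2)))
  if (total == 0) {
    warning("directness undefined: zero total distance")
    return(NA_real_)
  }
  n <- length(track$x)
  disp <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  disp / total
}

#' Migration speed of a track
#'
#' Total path length divided by observed elapsed time, in micrometres per
#' minute ("speed in any direction"). The denominator is the observed
#' `t_last - t_first`, so truncated tracks are handled honestly rather than
#' assuming the nominal assay duration.
#'
#' @inheritParams step_vectors
#' @return Speed in um/min (>= 0).
#' @export
track_speed <- function(track) {
  sv <- step_vectors(track)
  minutes <- (track$t[length(track$t)] - track$t[1]) / 60
  if (minutes <= 0) stop("zero elapsed time")
  sum(sqrt(rowSums(sv^2))) / minutes
}

#' Migration velocity of a track toward the chemoattractant
#'
#' Signed net drift along the gradient axis: the net displacement vector
#' projected onto the gradient direction, divided by elapsed time. Positive
#' values are toward the chemoattractant source.
#'
#' @inheritParams chemotactic_index
#' @return Velocity in um/min (signed); its magnitude never exceeds the speed.
#' @export
track_velocity <- function(track, gradient = gradient_spec()) {
  g <- as_gradient(gradient)
  n <- length(track$x)
  minutes <- (track$t[n] - track$t[1]) / 60
  if (minutes <= 0) stop("zero elapsed time")
  net <- c(track$x[n] - track$x[1], track$y[n] - track$y[1])
  sum(net * g) / minutes
}

#' All migration metrics for one track
#'
#' @inheritParams chemotactic_index
#' @return A one-row data.frame: `track_id`, `speed` and `velocity` (um/min),
#'   `chemotactic_index`, `directness`, `displacement` and `distance` (um),
#'   `n_steps_used` (nonzero steps entering the chemotactic index) and
#'   `n_zero_steps`.
#' @export
track_metrics <- function(track, gradient = gradient_spec()) {
  sv <- step_vectors(track)
  len <- sqrt(rowSums(sv^2))
  n <- length(track$x)
  disp <- sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
  ci <- if (any(len > 0)) chemotactic_index(track, gradient) else NA_real_
  dir <- if (sum(len) > 0) directness(track) else NA_real_
  data.frame(
    track_id = track$track_id,
    speed = track_speed(track),
    velocity = track_velocity(track, gradient),
    chemotactic_index = ci,
    directness = dir,
    displacement = disp,
    distance = sum(len),
    n_steps_used = sum(len > 0),
    n_zero_steps = sum(len == 0),
    stringsAsFactors = FALSE
  )
}

#' Per-cell metrics and subject-level summary for a set of tracks
#'
#' Computes [track_metrics()] for every track, drops cells with fewer than
#' `min_steps` steps (short tracks carry little directional information), and
#' summarises the survivors as an unweighted mean per metric — one value per
#' subject, matching how migration assays report a dot per participant.
#'
#' @param tracks list of [track()] objects from one subject.
#' @param gradient gradient direction, as in [chemotactic_index()].
#' @param min_steps minimum number of steps (points - 1) for a cell to enter
#'   the subject summary. Default 10.
#' @return A list with `per_cell` (data.frame of surviving cells' metrics),
#'   `subject` (one-row data.frame of means plus `n_cells_used`) and
#'   `n_filtered`.
#' @export
summarize_tracks <- function(tracks, gradient = gradient_spec(),
                             min_steps = 10) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  n_steps <- vapply(tracks, function(tr) length(tr$t) - 1L, integer(1))
  keep <- n_steps >= min_steps
  if (!any(keep))
    stop("empty subject: no track has at least ", min_steps, " steps")
  per_cell <- do.call(rbind, lapply(tracks[keep], track_metrics,
                                    gradient = gradient))
  num <- c("speed", "velocity", "chemotactic_index", "directness",
           "displacement", "distance")
  subject <- as.data.frame(lapply(per_cell[num],
                                  function(v) mean(v, na.rm = TRUE)))
  subject$n_cells_used <- nrow(per_cell)
  list(per_cell = per_cell, subject = subject,
       n_filtered = sum(!keep))
}
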