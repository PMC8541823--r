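#' Per-frame larva track
#'
#' Time series exported by a FIMtrack-style larva tracker: centroid position,
#' projected body area, spine length (head to tail) and mid-spine width, at a
#' constant frame rate (12.5 frames/s by default).
#'
#' @param x,y centroid coordinates in mm.
#' @param area projected larva area in mm^2 per frame, > 0.
#' @param spine_length head-to-tail spine length in mm (optional).
#' @param width diameter of the mid-spine circle in mm (optional).
#' @param fps frame rate in frames/s (default 12.5).
#' @param larva_id label.
#' @return An object of class `larva_track` with `frame_times` computed from
#'   `fps` and `qc_flags` initialized to `FALSE`.
#' @export
larva_track <- function(x, y, area, spine_length = NULL, width = NULL,
                        fps = 12.5, larva_id = "larva") {
  n <- length(x)
  if (length(y) != n || length(area) != n)
    stop("larva_track: x, y, area must have equal length", call. = FALSE)
  if (!is.null(spine_length) && length(spine_length) != n)
    stop("larva_track: spine_length length mismatch", call. = FALSE)
  if (!is.null(width) && length(width) != n)
    stop("larva_track: width length mismatch", call. = FALSE)
  if (any(area <= 0, na.rm = TRUE))
    stop("larva_track: area must be > 0", call. = FALSE)
  structure(
    list(frame_times = (seq_len(n) - 1) / fps, fps = fps,
         x = as.numeric(x), y = as.numeric(y), area = as.numeric(area),
         spine_length = spine_length, width = width,
         qc_flags = c(burrowed = FALSE, escaped = FALSE),
         larva_id = larva_id),
    class = "larva_track"
  )
}

#' @export
print.larva_track <- function(x, ...) {
  cat(sprintf("<larva_track> %s: %d frames at %g fps (%.1f s)\n",
              x$larva_id, length(x$x), x$fps, length(x$x) / x$fps))
  invisible(x)
}

#' Savitzky-Golay smoothing of the larval area series
#'
#' Least-squares local-polynomial smoothing of the area-vs-time curve, the
#' standard denoising step before counting peristaltic waves as area peaks.
#' Defaults (window 11 frames ~ 0.9 s at 12.5 fps, polynomial order 3) follow
#' common practice for larval crawling at this frame rate.
#'
#' @param track a [larva_track], or a bare numeric series.
#' @param window odd filter length in frames, > `polyorder` and <= series
#'   length.
#' @param polyorder polynomial order.
#' @return Smoothed numeric series, same length as the input.
#' @export
smooth_area <- function(track, window = 11L, polyorder = 3L) {
  a <- if (inherits(track, "larva_track")) track$area else as.numeric(track)
  if (window %% 2 == 0 || window <= polyorder || window > length(a))
    stop("smooth_area: need odd window, > polyorder and <= series length",
         call. = FALSE)
  as.numeric(signal::sgolayfilt(a, p = polyorder, n = window))
}

# peak prominence: for each local maximum, height above the higher of the two
# lowest valleys separating it from taller terrain (or the series ends)
local_peaks_with_prominence <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  # strict rise then fall (plateau peaks take their first frame)
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx <- idx[x[idx] > x[idx - 1L]]
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher <- which(left > h)
    lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, i - 1L)])
    right <- x[seq.int(i + 1L, n)]
    higher <- which(right > h)
    rmin <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Count peristaltic waves as peaks of the smoothed area curve
#'
#' One peristaltic contraction cycle produces one oscillation of the projected
#' larva area, so the wave count is the number of area peaks. A peak must have
#' a prominence of at least `min_prominence_iqr` times the interquartile range
#' of the smoothed series (robust to the amplitude scale) and at least
#' `min_prominence_median` times the series median: a peristaltic contraction
#' modulates the projected area by tens of percent, so sub-percent ripples
#' surviving the smoothing are noise, not waves, even when the larva is
#' otherwise motionless. Both thresholds are invariant under positive
#' rescaling of the area series.
#'
#' @param smoothed numeric smoothed area series (see [smooth_area()]).
#' @param min_prominence_iqr prominence threshold as a multiple of the series
#'   IQR (default 0.25).
#' @param min_prominence_median prominence floor as a multiple of the series
#'   median (default 0.05; ignored when the median is not positive).
#' @return Integer number of waves; a constant series yields 0.
#' @export
count_peristaltic_waves <- function(smoothed, min_prominence_iqr = 0.25,
                                    min_prominence_median = 0.05) {
  x <- as.numeric(smoothed)
  if (length(x) < 3) stop("count_peristaltic_waves: series too short", call. = FALSE)
  pk <- local_peaks_with_prominence(x)
  if (nrow(pk) == 0) return(0L)
  iqr <- stats::IQR(x)
  if (iqr == 0) return(0L)
  thr <- min_prominence_iqr * iqr
  med <- stats::median(x)
  if (med > 0) thr <- max(thr, min_prominence_median * med)
  sum(pk$prominence >= thr)
}

#' Distance traveled by the larva
#'
#' @param track a [larva_track] with at least two frames.
#' @return Total path length in mm (sum of successive Euclidean centroid
#'   displacements).
#' @export
traveled_distance <- function(track) {
  if (length(track$x) < 2)
    stop("traveled_distance: need >= 2 frames", call. = FALSE)
  bad <- which(!is.finite(track$x) | !is.finite(track$y))
  if (length(bad))
    stop(sprintf("traveled_distance: non-finite coordinates at frames %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Stride metrics from distance, wave count and recording time
#'
#' Stride size is the distance crawled during one peristaltic wave
#' (`distance / n_waves`); stride duration is the recording time divided by
#' the number of waves. With zero waves both are reported as `NA` with a QC
#' flag rather than an error.
#'
#' @param track a [larva_track].
#' @param n_waves wave count, e.g. from [count_peristaltic_waves()].
#' @param recording_time recording time in s; defaults to the track span.
#' @return A list of class `stride_metrics`: `distance` (mm), `n_waves`,
#'   `stride_size` (mm/wave), `stride_duration` (s/wave), `recording_time`
#'   (s), `undefined` (TRUE when `n_waves == 0`).
#' @export
stride_metrics <- function(track, n_waves,
                           recording_time = length(track$x) / track$fps) {
  if (n_waves < 0) stop("stride_metrics: n_waves must be >= 0", call. = FALSE)
  d <- traveled_distance(track)
  if (n_waves == 0) {
    out <- list(distance = d, n_waves = 0L, stride_size = NA_real_,
                stride_duration = NA_real_, recording_time = recording_time,
                undefined = TRUE)
  } else {
    out <- list(distance = d, n_waves = as.integer(n_waves),
                stride_size = d / n_waves,
                stride_duration = recording_time / n_waves,
                recording_time = recording_time, undefined = FALSE)
  }
  structure(out, class = "stride_metrics")
}

#' Time-averaged larva body dimensions
#'
#' @param track a [larva_track] carrying spine length and width series.
#' @return List with `mean_length` and `mean_width` in mm (NA when the series
#'   is absent).
#' @export
body_dimensions <- function(track) {
  list(
    mean_length = if (is.null(track$spine_length)) NA_real_
                  else mean(track$spine_length),
    mean_width = if (is.null(track$width)) NA_real_ else mean(track$width)
  )
}

#' Quality-control exclusion flags
#'
#' Larvae that escape the arena or burrow into the agar must be excluded.
#' Escape is flagged when the centroid leaves the arena bounds. Burrowing is
#' detected by proxy: the projected area collapsing below a fraction of its
#' median for a sustained window (a buried larva presents little area to the
#' camera).
#'
#' @param track a [larva_track].
#' @param arena_bounds numeric `c(xmin, xmax, ymin, ymax)` in mm.
#' @param area_collapse_frac area fraction of the median counting as collapsed
#'   (default 0.5).
#' @param min_collapse_s minimum sustained collapse duration in s (default 2).
#' @return Named logical vector `c(burrowed =, escaped =)`.
#' @export
qc_exclude <- function(track, arena_bounds, area_collapse_frac = 0.5,
                       min_collapse_s = 2) {
  if (length(arena_bounds) != 4)
    stop("qc_exclude: arena_bounds must be c(xmin, xmax, ymin, ymax)",
         call. = FALSE)
  escaped <- any(track$x < arena_bounds[1] | track$x > arena_bounds[2] |
                 track$y < arena_bounds[3] | track$y > arena_bounds[4])
  low <- track$area < area_collapse_frac * stats::median(track$area)
  r <- rle(low)
  burrowed <- any(r$values & r$lengths >= ceiling(min_collapse_s * track$fps))
  c(burrowed = burrowed, escaped = escaped)
}

#' Full per-larva locomotion analysis
#'
#' Convenience wrapper running the standard chain: Savitzky-Golay smoothing of
#' the area curve, prominence-based wave counting, traveled distance, stride
#' metrics and body dimensions.
#'
#' @param track a [larva_track].
#' @param recording_time recording time in s (default 120).
#' @param window,polyorder see [smooth_area()].
#' @param min_prominence_iqr see [count_peristaltic_waves()].
#' @return One-row data.frame with columns `larva_id`, `distance_mm`,
#'   `n_waves`, `stride_size_mm`, `stride_duration_s`, `mean_length_mm`,
#'   `mean_width_mm`, `qc_burrowed`, `qc_escaped`.
#' @export
analyze_locomotion <- function(track, recording_time = 120, window = 11L,
                               polyorder = 3L, min_prominence_iqr = 0.25) {
  sm <- smooth_area(track, window = window, polyorder = polyorder)
  nw <- count_peristaltic_waves(sm, min_prominence_iqr = min_prominence_iqr)
  m <- stride_metrics(track, nw, recording_time = recording_time)
  dims <- body_dimensions(track)
  data.frame(
    larva_id = track$larva_id, distance_mm = m$distance, n_waves = m$n_waves,
    stride_size_mm = m$stride_size, stride_duration_s = m$stride_duration,
    mean_length_mm = dims$mean_length, mean_width_mm = dims$mean_width,
    qc_burrowed = track$qc_flags[["burrowed"]],
    qc_escaped = track$qc_flags[["escaped"]],
    stringsAsFactors = FALSE
  )
}
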