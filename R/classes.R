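#' Fluorescence movie stack
#'
#' Container for a time series of two-photon fluorescence frames. Pixel
#' values are in arbitrary fluorescence units; frames are stored as a
#' 3-D array indexed `[row, col, frame]`.
#'
#' @param data numeric 3-D array, `rows x cols x frames`, or a matrix for
#'   a single frame.
#' @param frame_rate_hz positive scan rate in frames per second. Typical
#'   acquisition rates for the recordings this package targets are 0.74
#'   or 1.7 Hz.
#' @param t0_s time of the first frame in seconds (shared origin with the
#'   electrophysiology trace).
#' @return An object of class `movie_stack` with elements `data`,
#'   `frame_rate_hz`, `t0_s`.
#' @export
movie_stack <- function(data, frame_rate_hz, t0_s = 0) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3] < 1L) stop("movie must contain at least one frame")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a positive scalar")
  }
  structure(
    list(data = data, frame_rate_hz = frame_rate_hz, t0_s = t0_s),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "movie_stack: %d frames of %d x %d px at %.3g Hz (%.1f s, t0 = %.1f s)\n",
    d[3], d[1], d[2], x$frame_rate_hz, d[3] / x$frame_rate_hz, x$t0_s
  ))
  invisible(x)
}

#' Frame times of a movie
#'
#' @param movie a `movie_stack`.
#' @return Numeric vector of frame onset times in seconds.
#' @export
frame_times <- function(movie) {
  movie$t0_s + (seq_len(dim(movie$data)[3]) - 1L) / movie$frame_rate_hz
}

#' Number of frames in a movie
#' @param movie a `movie_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' ROI map
#'
#' A labelled image plus per-ROI records. Label 0 is background; ROI `k`
#' occupies the pixels where `labels == k`. Pixel coordinates follow R
#' matrix convention (`row`, `col`), 1-based.
#'
#' @param labels integer matrix, 0 for background, `k` for ROI `k`.
#' @param rois data.frame with one row per ROI: `id`, `shape_class`
#'   (`"stalk"`, `"lateral_process"` or `"grid"`), `area_px`,
#'   `circularity`, `aspect_ratio`.
#' @param pixels list of integer vectors of linear pixel indices into
#'   `labels`, one per ROI, in the same order as `rois`.
#' @return An object of class `roi_map`.
#' @export
roi_map <- function(labels, rois, pixels) {
  stopifnot(is.matrix(labels), nrow(rois) == length(pixels))
  if (nrow(rois) > 0) {
    stopifnot(identical(sort(rois$id), sort(unique(rois$id))))
    all_px <- unlist(pixels, use.names = FALSE)
    if (anyDuplicated(all_px)) stop("ROIs must be pairwise disjoint")
  }
  structure(
    list(labels = labels, rois = rois, pixels = pixels),
    class = "roi_map"
  )
}

#' @export
print.roi_map <- function(x, ...) {
  tab <- table(x$rois$shape_class)
  cat(sprintf(
    "roi_map: %d ROIs on a %d x %d field (%s)\n",
    nrow(x$rois), nrow(x$labels), ncol(x$labels),
    if (length(tab)) paste(names(tab), as.integer(tab), collapse = ", ")
    else "empty"
  ))
  invisible(x)
}

#' Number of ROIs in a map
#' @param rois a `roi_map` or a plain ROI count.
#' @return Integer number of ROIs.
#' @export
n_rois <- function(rois) {
  if (inherits(rois, "roi_map")) nrow(rois$rois)
  else as.integer(rois)
}

#' Per-ROI fluorescence traces
#'
#' Holds per-ROI mean-intensity time series and, once [compute_dff()] has
#' been applied, the normalised dF/F traces with their baseline F0.
#' The defining identity is `dff = (raw_mean - f0) / f0`, column-wise.
#'
#' @param roi_ids integer vector of ROI ids.
#' @param t_s frame times in seconds.
#' @param raw_mean numeric matrix `frames x rois` of ROI-mean intensity.
#' @param dff optional matrix of the same shape with dF/F values.
#' @param f0 optional per-ROI baseline fluorescence (positive).
#' @param frame_rate_hz frame rate the traces were sampled at.
#' @return An object of class `dff_traces`.
#' @export
dff_traces <- function(roi_ids, t_s, raw_mean, dff = NULL, f0 = NULL,
                       frame_rate_hz) {
  raw_mean <- as.matrix(raw_mean)
  stopifnot(length(t_s) == nrow(raw_mean),
            length(roi_ids) == ncol(raw_mean))
  if (!is.null(f0) && any(f0 <= 0)) stop("f0 must be positive")
  structure(
    list(roi_ids = as.integer(roi_ids), t_s = t_s, raw_mean = raw_mean,
         dff = dff, f0 = f0, frame_rate_hz = frame_rate_hz),
    class = "dff_traces"
  )
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf(
    "dff_traces: %d ROIs x %d frames at %.3g Hz (%s)\n",
    ncol(x$raw_mean), nrow(x$raw_mean), x$frame_rate_hz,
    if (is.null(x$dff)) "raw only" else "dF/F computed"
  ))
  invisible(x)
}

#' Whole-cell current trace
#'
#' Uniformly sampled voltage-clamp current from a retinal ganglion cell.
#' Inward (excitatory, at negative holding potential) currents are
#' negative by convention.
#'
#' @param time_s sample times in seconds (uniform).
#' @param current_pA signed current in picoamperes.
#' @param sample_rate_hz sampling rate.
#' @param holding_mV holding potential; -60 mV by convention.
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(time_s, current_pA, sample_rate_hz,
                        holding_mV = -60) {
  stopifnot(length(time_s) == length(current_pA))
  if (length(time_s) > 2) {
    dt <- diff(time_s)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
      stop("ephys trace must be uniformly sampled")
    }
  }
  structure(
    list(time_s = time_s, current_pA = current_pA,
         sample_rate_hz = sample_rate_hz, holding_mV = holding_mV),
    class = "ephys_trace"
  )
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf(
    "ephys_trace: %.1f s at %g Hz, holding %g mV, range [%.1f, %.1f] pA\n",
    diff(range(x$time_s)), x$sample_rate_hz, x$holding_mV,
    min(x$current_pA), max(x$current_pA)
  ))
  invisible(x)
}

#' Simulation ground truth
#'
#' Book-keeping produced by the synthetic experiment generator: true wave
#' onsets, the set of ROIs recruited by each wave, the per-ROI event
#' onsets, and the per-wave recruited fraction. Used by recovery tests to
#' score the analysis pipeline.
#'
#' @param wave_onsets_s numeric vector of wave onset times.
#' @param recruited list (one element per wave) of integer ROI ids.
#' @param event_onsets named list, ROI id -> numeric onset times.
#' @param n_rois total number of ROIs in the layout.
#' @param frame_shifts optional integer matrix `frames x 2` of the true
#'   (dy, dx) scene drift applied to each frame.
#' @return An object of class `ground_truth`; the element
#'   `true_participation_per_wave` holds `|recruited[w]| / n_rois`.
#' @export
ground_truth <- function(wave_onsets_s, recruited, event_onsets, n_rois,
                         frame_shifts = NULL) {
  stopifnot(length(recruited) == length(wave_onsets_s))
  structure(
    list(
      wave_onsets_s = wave_onsets_s,
      recruited = recruited,
      event_onsets = event_onsets,
      n_rois = as.integer(n_rois),
      true_participation_per_wave =
        vapply(recruited, length, 1L) / max(1L, n_rois),
      frame_shifts = frame_shifts
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d waves, %d ROIs, %d events\n",
    length(x$wave_onsets_s), x$n_rois,
    sum(lengths(x$event_onsets))
  ))
  invisible(x)
}
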