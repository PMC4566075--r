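#' Extract per-ROI mean-intensity traces
#'
#' The fluorescence of an ROI at each frame is the average pixel value
#' over its area.
#'
#' @param movie a [movie_stack()].
#' @param rois a [roi_map()]; all ROI pixels must lie inside the frame.
#' @return A [dff_traces()] object at the raw stage (no dF/F yet).
#' @export
extract_traces <- function(movie, rois) {
  d <- dim(movie$data)
  if (!identical(dim(rois$labels), d[1:2])) {
    stop("ROI map (", nrow(rois$labels), " x ", ncol(rois$labels),
         ") does not fit the movie frame (", d[1], " x ", d[2], ")")
  }
  nf <- d[3]; npx <- d[1] * d[2]
  nr <- nrow(rois$rois)
  raw <- matrix(NA_real_, nf, nr)
  m <- matrix(movie$data, nrow = npx, ncol = nf)
  for (k in seq_len(nr)) {
    px <- rois$pixels[[k]]
    raw[, k] <- colMeans(m[px, , drop = FALSE])
  }
  dff_traces(rois$rois$id, frame_times(movie), raw,
             frame_rate_hz = movie$frame_rate_hz)
}

#' Normalise traces to dF/F
#'
#' Applies `dF/F = (F - F0) / F0` per ROI, where `F` is the
#' instantaneous ROI-mean fluorescence and `F0` its baseline.
#'
#' @param traces a [dff_traces()] with raw means.
#' @param f0_method `"percentile"` (default; the 10th percentile of each
#'   ROI's raw trace, robust to sparse transients), `"mean_of_first_n"`
#'   (mean of the first `n_baseline` frames), or `"external"` (use the
#'   supplied `f0`).
#' @param percentile baseline percentile for the default method.
#' @param n_baseline frame count for `"mean_of_first_n"`.
#' @param f0 per-ROI baseline for `"external"`.
#' @return The input with `dff` and `f0` filled in.
#' @export
compute_dff <- function(traces,
                        f0_method = c("percentile", "mean_of_first_n",
                                      "external"),
                        percentile = 0.1, n_baseline = 10L, f0 = NULL) {
  f0_method <- match.arg(f0_method)
  raw <- traces$raw_mean
  f0 <- switch(f0_method,
    percentile = apply(raw, 2, stats::quantile, probs = percentile,
                       names = FALSE),
    mean_of_first_n = colMeans(raw[seq_len(min(n_baseline, nrow(raw))), ,
                                   drop = FALSE]),
    external = {
      if (is.null(f0)) stop("f0 must be supplied for f0_method='external'")
      rep_len(f0, ncol(raw))
    }
  )
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop("non-positive baseline F0 for ROI ",
         paste(traces$roi_ids[bad], collapse = ", "))
  }
  traces$f0 <- f0
  traces$dff <- sweep(sweep(raw, 2, f0, "-"), 2, f0, "/")
  traces
}

#' Binomial (Gaussian-approximating) smoothing kernel
#'
#' @param width odd kernel width; the coefficients are the binomial
#'   coefficients of order `width - 1`, normalised to sum to 1.
#' @return Numeric kernel of length `width`.
#' @export
binomial_kernel <- function(width) {
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  k <- choose(width - 1L, 0:(width - 1L))
  k / sum(k)
}

#' Smooth a trace by binomial filtering
#'
#' Convolves the trace with the normalised binomial kernel of the given
#' width; edges are handled by reflection, so a constant trace is
#' unchanged.
#'
#' @param trace numeric vector.
#' @param width odd kernel width; `1` is the identity.
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(trace, width = 3L) {
  n <- length(trace)
  if (width > n) stop("smoothing width exceeds trace length")
  if (width == 1L) return(trace)
  k <- binomial_kernel(width)
  h <- (width - 1L) %/% 2L
  padded <- c(trace[(h + 1L):2L], trace, trace[(n - 1L):(n - h)])
  stats::filter(padded, k, sides = 2)[(h + 1L):(h + n)]
}

#' Transient detection parameters
#'
#' @param k_multiplier SD multiple for the derivative threshold. `NULL`
#'   (default) selects the standard regime for the frame rate: 2 at
#'   rates up to 1 Hz (e.g. 0.74 Hz), 4 above (e.g. 1.7 Hz); focal-
#'   stimulation mode uses 2.5.
#' @param smooth_width binomial smoothing width (frames, odd).
#' @param min_separation_s events with onsets closer than this are
#'   merged.
#' @param min_peak_dff amplitude floor: a candidate event is kept only if
#'   its peak rises at least this far (in dF/F units) above its onset
#'   level. 0.05 is well below glial transient amplitudes but several
#'   noise SDs above a quiet ROI-mean trace at typical imaging SNR.
#' @param mode `"spontaneous"` or `"focal"`.
#' @param sd_window optional `(start_s, end_s)` quiet window over which
#'   the derivative SD is estimated; default uses the whole recording.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(k_multiplier = NULL, smooth_width = 3L,
                             min_separation_s = 5, min_peak_dff = 0.05,
                             mode = c("spontaneous", "focal"),
                             sd_window = NULL) {
  mode <- match.arg(mode)
  if (!is.null(k_multiplier) && k_multiplier <= 0) {
    stop("k_multiplier must be positive")
  }
  structure(
    list(k_multiplier = k_multiplier, smooth_width = as.integer(smooth_width),
         min_separation_s = min_separation_s, min_peak_dff = min_peak_dff,
         mode = mode, sd_window = sd_window),
    class = "detection_params"
  )
}

# an onset crossing at derivative step i (between frames i and i+1)
# dates the event from frame i+1, the first sample of the rising
# transient; this keeps detected onsets at or after the true departure
# from baseline up to one frame of smoothing spread

# the printed threshold regimes: 2 x SD up to 1 Hz, 4 x SD above;
# 2.5 x SD for focal-stimulation recordings
default_k_multiplier <- function(frame_rate_hz, mode = "spontaneous") {
  if (mode == "focal") return(2.5)
  if (frame_rate_hz <= 1.0) 2.0 else 4.0
}

#' Detect fluorescence transients by derivative threshold
#'
#' Per ROI: the dF/F trace is binomially smoothed, its first derivative
#' (first difference scaled by the frame interval) is taken, and onsets
#' are marked where the derivative first exceeds `k` times its standard
#' deviation (strictly greater; `k` as in [detection_params()]). The
#' event peak is the next local maximum of the smoothed dF/F; the offset
#' is the first later frame at which dF/F has returned below half of the
#' peak-above-onset amplitude (or the last frame). Candidate events whose
#' peak amplitude is below `min_peak_dff` are discarded, and events with
#' onsets closer than `min_separation_s` are merged.
#'
#' @param traces a [dff_traces()] with `dff` computed.
#' @param params a [detection_params()].
#' @return A data.frame of events with columns `roi_id`, `onset_s`,
#'   `peak_s`, `offset_s`, `peak_dff`, `duration_s`.
#' @export
detect_transients <- function(traces, params = detection_params()) {
  if (is.null(traces$dff)) stop("run compute_dff() before detection")
  if (nrow(traces$dff) < 3L) stop("need at least 3 frames for detection")
  k <- params$k_multiplier
  if (is.null(k)) k <- default_k_multiplier(traces$frame_rate_hz, params$mode)
  dt <- 1 / traces$frame_rate_hz
  t_s <- traces$t_s
  out <- vector("list", ncol(traces$dff))
  for (r in seq_len(ncol(traces$dff))) {
    x <- traces$dff[, r]
    if (all(is.na(x))) stop("all-NaN trace for ROI ", traces$roi_ids[r])
    x <- smooth_trace(x, min(params$smooth_width, length(x) -
                               (1 - length(x) %% 2)))
    d <- diff(x) / dt
    sd_idx <- seq_along(d)
    if (!is.null(params$sd_window)) {
      mid <- (t_s[-1] + t_s[-length(t_s)]) / 2
      sd_idx <- which(mid >= params$sd_window[1] & mid <= params$sd_window[2])
      if (length(sd_idx) < 2L) sd_idx <- seq_along(d)
    }
    sdd <- stats::sd(d[sd_idx])
    if (!is.finite(sdd) || sdd == 0) { out[[r]] <- NULL; next }
    above <- d > k * sdd
    onset_idx <- which(above & !c(FALSE, above[-length(above)]))
    if (!length(onset_idx)) { out[[r]] <- NULL; next }
    ev <- lapply(onset_idx, function(i) {
      # peak: next local maximum of the smoothed trace at/after onset + 1
      j <- i + 1L
      while (j < length(x) && x[j + 1L] > x[j]) j <- j + 1L
      base <- x[i]
      amp <- x[j] - base
      if (amp < params$min_peak_dff) return(NULL)
      # offset: return below half of peak-above-onset
      off <- j
      while (off < length(x) && x[off] > base + 0.5 * amp) off <- off + 1L
      data.frame(roi_id = traces$roi_ids[r], onset_s = t_s[i + 1L],
                 peak_s = t_s[j], offset_s = t_s[off],
                 peak_dff = x[j], amp_dff = amp)
    })
    ev <- do.call(rbind, ev)
    if (is.null(ev) || !nrow(ev)) { out[[r]] <- NULL; next }
    # merge events with onsets closer than min_separation_s
    keep <- list(ev[1, ])
    if (nrow(ev) > 1) {
      for (i in 2:nrow(ev)) {
        last <- keep[[length(keep)]]
        if (ev$onset_s[i] - last$onset_s < params$min_separation_s) {
          last$offset_s <- max(last$offset_s, ev$offset_s[i])
          if (ev$peak_dff[i] > last$peak_dff) {
            last$peak_dff <- ev$peak_dff[i]
            last$peak_s <- ev$peak_s[i]
          }
          keep[[length(keep)]] <- last
        } else {
          keep[[length(keep) + 1L]] <- ev[i, ]
        }
      }
    }
    out[[r]] <- do.call(rbind, keep)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) {
    ev <- data.frame(roi_id = integer(0), onset_s = numeric(0),
                     peak_s = numeric(0), offset_s = numeric(0),
                     peak_dff = numeric(0))
  }
  ev$amp_dff <- NULL
  ev$duration_s <- ev$offset_s - ev$onset_s
  rownames(ev) <- NULL
  ev
}
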