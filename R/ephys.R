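#' Detect retinal-wave epochs from a current trace
#'
#' Retinal waves appear in a voltage-clamped ganglion cell as compound
#' inward (negative) excitatory postsynaptic currents. The trace is
#' smoothed with a short moving average, a baseline is taken as the
#' median, and epochs are maximal runs below
#' `baseline - c_threshold * robust SD` (robust SD = 1.4826 * MAD)
#' lasting at least `min_dur_s`; runs separated by less than
#' `merge_gap_s` are merged. Because both the baseline and the spread are
#' scale-covariant, scaling the trace by a positive constant leaves the
#' detected epochs unchanged.
#'
#' @param trace an [ephys_trace()] (uniform sampling required).
#' @param c_threshold robust-SD multiple below baseline.
#' @param min_dur_s minimum epoch duration in seconds.
#' @param merge_gap_s sub-threshold runs closer than this are merged.
#' @param smooth_s moving-average width in seconds applied before
#'   thresholding.
#' @return A data.frame of epochs: `onset_s`, `offset_s`,
#'   `peak_current_pA` (most negative value), `charge_pC` (trapezoidal
#'   integral of baseline-subtracted inward current, reported positive).
#' @export
detect_wave_epochs <- function(trace, c_threshold = 4, min_dur_s = 1,
                               merge_gap_s = 2, smooth_s = 0.2) {
  t <- trace$time_s
  x <- trace$current_pA
  if (length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
      stop("wave detection requires uniform sampling")
    }
  }
  dt <- 1 / trace$sample_rate_hz
  w <- max(1L, round(smooth_s * trace$sample_rate_hz))
  xs <- if (w > 1L) {
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  } else x
  # moving average leaves NA at the edges; fall back to the raw values
  xs[is.na(xs)] <- x[is.na(xs)]
  baseline <- stats::median(xs)
  rsd <- stats::mad(xs)
  thr <- baseline - c_threshold * rsd
  below <- xs < thr
  if (!any(below)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_current_pA = numeric(0), charge_pC = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if ((runs$start[i] - last$end - 1L) * dt < merge_gap_s) {
        last$end <- runs$end[i]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- runs[i, ]
      }
    }
  }
  runs <- do.call(rbind, merged)
  runs <- runs[(runs$end - runs$start + 1L) * dt >= min_dur_s, , drop = FALSE]
  if (!nrow(runs)) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak_current_pA = numeric(0), charge_pC = numeric(0)))
  }
  epochs <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    seg <- x[idx] - baseline
    seg[seg > 0] <- 0
    data.frame(
      onset_s = t[runs$start[i]],
      offset_s = t[runs$end[i]],
      peak_current_pA = min(x[idx]),
      # inward charge, sign flipped so the reported charge is positive
      charge_pC = -sum((seg[-1] + seg[-length(seg)]) / 2) * dt
    )
  }))
  rownames(epochs) <- NULL
  epochs
}

#' Focal-stimulation protocol
#'
#' Represents repeated short pressure applications of an agonist (for
#' example 100 ms puffs of 1 mM L-glutamate or acetylcholine) at the
#' IPL/GCL border.
#'
#' @param application_times_s strictly increasing application onsets.
#' @param duration_s duration of each application (default 0.1 s).
#' @param agent label for the applied agent.
#' @return A list of class `stim_protocol`.
#' @export
stim_protocol <- function(application_times_s, duration_s = 0.1,
                          agent = "ACSF") {
  if (length(application_times_s) > 1 &&
      any(diff(application_times_s) <= 0)) {
    stop("application times must be strictly increasing")
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  structure(
    list(application_times_s = application_times_s,
         duration_s = duration_s, agent = agent),
    class = "stim_protocol"
  )
}

#' Analysis windows for focal applications
#'
#' @param protocol a [stim_protocol()].
#' @param window_s length of the evoked-response analysis window after
#'   each application onset (default 10 s).
#' @return A data.frame of intervals `start_s`, `end_s`, one per
#'   application; overlapping windows trigger a warning, not an error.
#' @export
focal_stim_epochs <- function(protocol, window_s = 10) {
  ts <- protocol$application_times_s
  if (!length(ts)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  win <- data.frame(start_s = ts, end_s = ts + window_s)
  if (nrow(win) > 1 && any(win$start_s[-1] < win$end_s[-nrow(win)])) {
    warning("focal stimulation windows overlap")
  }
  win
}
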