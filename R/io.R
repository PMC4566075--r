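#' Write a movie as multi-frame TIFF
#'
#' One 16-bit unsigned page per frame. Pixel values are rounded and
#' clamped to `[0, 65535]`; values already on that integer grid
#' round-trip exactly.
#'
#' @param movie a [movie_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  nf <- n_frames(movie)
  pages <- lapply(seq_len(nf), function(f) {
    m <- round(movie$data[, , f])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' @param path TIFF file written by [write_movie_tiff()] or any
#'   single-channel multi-page TIFF.
#' @param frame_rate_hz frame rate to attach (not stored in the TIFF).
#' @param t0_s time of the first frame.
#' @return A [movie_stack()] with 16-bit integer pixel values.
#' @export
read_movie_tiff <- function(path, frame_rate_hz, t0_s = 0) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("cannot parse TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    round(p * 65535)
  })
  d <- dim(pages[[1]])
  data <- array(unlist(pages, use.names = FALSE),
                dim = c(d[1], d[2], length(pages)))
  movie_stack(data, frame_rate_hz, t0_s)
}

#' Write / read an ephys trace as CSV
#'
#' CSV with header `time_s,current_pA`, '.' decimal separator.
#'
#' @param trace an [ephys_trace()].
#' @param path CSV file.
#' @return `path` invisibly (write) or an [ephys_trace()] (read).
#' @export
write_ephys_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time_s, current_pA = trace$current_pA),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_ephys_csv
#' @param holding_mV holding potential to attach on read.
#' @export
read_ephys_csv <- function(path, holding_mV = -60) {
  if (!file.exists(path)) stop("ephys file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df))) {
    stop("'", path, "' lacks the time_s,current_pA header")
  }
  dt <- stats::median(diff(df$time_s))
  ephys_trace(df$time_s, df$current_pA, sample_rate_hz = 1 / dt,
              holding_mV = holding_mV)
}

#' Write / read ground truth as JSON
#'
#' @param truth a [ground_truth()].
#' @param path JSON file.
#' @return `path` invisibly (write) or a [ground_truth()] (read).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      wave_onsets_s = truth$wave_onsets_s,
      recruited = lapply(truth$recruited, as.integer),
      event_onsets = truth$event_onsets,
      n_rois = truth$n_rois,
      frame_shifts = truth$frame_shifts
    ),
    path, auto_unbox = FALSE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- x$event_onsets
  ev <- lapply(ev, as.numeric)
  rec <- x$recruited
  if (is.matrix(rec)) rec <- split(rec, row(rec))
  if (!is.list(rec)) rec <- as.list(rec)
  ground_truth(
    as.numeric(x$wave_onsets_s),
    lapply(rec, as.integer),
    ev, x$n_rois,
    frame_shifts = if (!is.null(x$frame_shifts)) {
      matrix(as.integer(as.matrix(x$frame_shifts)), ncol = 2,
             dimnames = list(NULL, c("dy", "dx")))
    }
  )
}

#' Write an ROI label image as TIFF
#'
#' @param rois a [roi_map()].
#' @param path output file; labels are stored as 16-bit values.
#' @return `path`, invisibly.
#' @export
write_roi_tiff <- function(rois, path) {
  tiff::writeTIFF(rois$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a detected-event table as CSV
#'
#' Columns `roi_id, onset_s, peak_s, offset_s, peak_dff, duration_s`.
#'
#' @param events event data.frame from [detect_transients()].
#' @param path CSV file.
#' @return `path` invisibly (write) or the event data.frame (read).
#' @export
write_events_csv <- function(events, path) {
  cols <- c("roi_id", "onset_s", "peak_s", "offset_s", "peak_dff",
            "duration_s")
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  utils::read.csv(path)
}
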