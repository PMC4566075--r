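# --- shape measurement helpers -------------------------------------------

# translate a frame by integer (dy, dx); vacated pixels get `fill`
translate_frame <- function(m, dy, dx, fill = stats::median(m)) {
  rows <- nrow(m); cols <- ncol(m)
  out <- matrix(fill, rows, cols)
  ys <- max(1L, 1L + dy):min(rows, rows + dy)
  xs <- max(1L, 1L + dx):min(cols, cols + dx)
  if (length(ys) && length(xs)) {
    out[ys, xs] <- m[ys - dy, xs - dx]
  }
  out
}

# boundary-pixel perimeter: pixels of the set with at least one
# 4-neighbour outside the set (or on the image border)
roi_perimeter_px <- function(labels, px, id) {
  rows <- nrow(labels)
  y <- ((px - 1L) %% rows) + 1L
  x <- ((px - 1L) %/% rows) + 1L
  inside <- function(yy, xx) {
    ok <- yy >= 1L & yy <= rows & xx >= 1L & xx <= ncol(labels)
    res <- logical(length(yy))
    res[ok] <- labels[(xx[ok] - 1L) * rows + yy[ok]] == id
    res
  }
  boundary <- !(inside(y - 1L, x) & inside(y + 1L, x) &
                  inside(y, x - 1L) & inside(y, x + 1L))
  sum(boundary)
}

# circularity 4*pi*A/P^2 (capped at 1) and best-fit-ellipse aspect ratio
# from second moments of the pixel set
roi_shape_stats <- function(labels, px, id) {
  rows <- nrow(labels)
  y <- ((px - 1L) %% rows) + 1L
  x <- ((px - 1L) %/% rows) + 1L
  a <- length(px)
  p <- roi_perimeter_px(labels, px, id)
  circ <- min(1, 4 * pi * a / p^2)
  if (a < 3L) {
    aspect <- 1
  } else {
    cv <- stats::cov(cbind(y, x)) + diag(1 / 12, 2)  # pixel variance
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    aspect <- sqrt(max(ev) / max(min(ev), 1e-12))
  }
  c(area = a, perimeter = p, circularity = circ, aspect_ratio = aspect)
}

# assemble the per-ROI data.frame for a label image
roi_table_from_pixels <- function(labels, pixels, shape_class = NULL) {
  n <- length(pixels)
  if (n == 0L) {
    return(data.frame(id = integer(0), shape_class = character(0),
                      area_px = integer(0), circularity = numeric(0),
                      aspect_ratio = numeric(0)))
  }
  stats <- t(vapply(seq_len(n), function(k) {
    roi_shape_stats(labels, pixels[[k]], k)
  }, numeric(4)))
  data.frame(
    id = seq_len(n),
    shape_class = if (is.null(shape_class)) rep(NA_character_, n)
                  else shape_class,
    area_px = as.integer(stats[, "area"]),
    circularity = stats[, "circularity"],
    aspect_ratio = stats[, "aspect_ratio"]
  )
}

# --- registration ---------------------------------------------------------

# integer-shift estimate of `frame` relative to `ref` by FFT
# cross-correlation, restricted to |shift| <= max_shift
estimate_shift <- function(ref, frame, max_shift) {
  rows <- nrow(ref); cols <- ncol(ref)
  r <- ref - mean(ref); f <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(r)), inverse = TRUE))
  sy <- c(0:max_shift, -(max_shift:1))
  sx <- c(0:max_shift, -(max_shift:1))
  iy <- c(1:(max_shift + 1), rows - (max_shift:1) + 1L)
  ix <- c(1:(max_shift + 1), cols - (max_shift:1) + 1L)
  win <- cc[iy, ix]
  k <- arrayInd(which.max(win), dim(win))
  c(dy = sy[k[1]], dx = sx[k[2]])
}

#' Register a movie against X-Y drift
#'
#' Estimates an integer-pixel translation for each frame by maximum
#' cross-correlation against a reference image and shifts each frame
#' back. Recordings in which the estimated shift ever exceeds
#' `reject_shift_px` are flagged as rejected, mirroring the practice of
#' discarding recordings whose plane of focus moved too far.
#'
#' @param movie a [movie_stack()].
#' @param reference `"first"` (default) registers against the first
#'   frame, giving shifts equal to the cumulative scene drift;
#'   `"mean10"` uses the mean of the first 10 frames.
#' @param max_shift_px search radius for the shift estimate.
#' @param reject_shift_px shifts beyond this bound raise the rejection
#'   flag (the movie is still returned registered).
#' @return A list: `movie` (registered [movie_stack()]), `shifts`
#'   (integer `frames x 2` matrix of estimated (dy, dx)), `rejected`
#'   (logical).
#' @export
register_movie <- function(movie, reference = c("first", "mean10"),
                           max_shift_px = 20L, reject_shift_px = 30L) {
  reference <- match.arg(reference)
  if (!all(is.finite(movie$data))) {
    stop("movie contains non-finite pixel values")
  }
  nf <- n_frames(movie)
  shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  if (nf < 2L) {
    return(list(movie = movie, shifts = shifts, rejected = FALSE))
  }
  ref <- if (reference == "first") {
    movie$data[, , 1]
  } else {
    apply(movie$data[, , seq_len(min(10L, nf)), drop = FALSE], c(1, 2), mean)
  }
  max_shift_px <- min(max_shift_px,
                      floor(min(dim(ref)) / 2) - 1L)
  out <- movie$data
  fill <- stats::median(movie$data[, , 1])
  for (f in seq_len(nf)) {
    s <- estimate_shift(ref, movie$data[, , f], max_shift_px)
    shifts[f, ] <- s
    if (any(s != 0L)) {
      out[, , f] <- translate_frame(movie$data[, , f], -s[1], -s[2],
                                    fill = fill)
    }
  }
  list(
    movie = movie_stack(out, movie$frame_rate_hz, movie$t0_s),
    shifts = shifts,
    rejected = any(abs(shifts) > reject_shift_px)
  )
}

# --- Laplacian segmentation ----------------------------------------------

# Laplacian-of-Gaussian kernel, zero-sum, sign-flipped so bright blobs
# give positive responses
log_kernel <- function(sigma) {
  s <- ceiling(3 * sigma)
  g <- expand.grid(y = -s:s, x = -s:s)
  r2 <- g$y^2 + g$x^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- matrix(k, 2 * s + 1, 2 * s + 1)
  -(k - mean(k))
}

#' Summary image of a movie
#'
#' @param movie a [movie_stack()].
#' @param method `"mean"` (temporal mean; suited to indicator-filled
#'   structures that are visible at rest) or `"sd"` (temporal standard
#'   deviation; suited to sparse sensors visible only when active).
#' @return A matrix the size of one frame.
#' @export
summary_image <- function(movie, method = c("mean", "sd")) {
  method <- match.arg(method)
  d <- movie$data
  nf <- dim(d)[3]
  m <- rowMeans(d, dims = 2)
  if (method == "mean") return(m)
  if (nf < 2L) return(m * 0)
  sqrt(pmax(rowSums((d - as.vector(m))^2, dims = 2) / (nf - 1), 0))
}

#' Segment ROIs by Laplacian filtering
#'
#' Applies a Laplacian-of-Gaussian band-pass to a summary image of the
#' movie and thresholds the filtered response at `mean + c * sd` to find
#' seed pixels at fluorescent structures. With `refine = TRUE` (default)
#' each seed is grown to the full bright structure supporting it: the
#' summary image is thresholded by Otsu's method and the connected
#' components of that support mask which contain at least one seed become
#' the ROIs. With `refine = FALSE` the thresholded filter response itself
#' is labelled. Components smaller than `min_area` are discarded.
#' Each ROI is classified as stalk or lateral process by
#' [classify_roi_shape()].
#'
#' @param movie a registered [movie_stack()].
#' @param sigma scale of the Laplacian-of-Gaussian, in pixels; should
#'   match the half-width of the thinnest structures of interest.
#' @param c_threshold threshold constant `c` on the filtered image.
#' @param min_area minimum ROI size in pixels.
#' @param summary_method passed to [summary_image()].
#' @param refine grow seeds to Otsu support components (see above).
#' @return A [roi_map()] with circularity and shape class per ROI; a
#'   blank or constant movie yields an empty map rather than an error.
#' @export
laplacian_roi_masks <- function(movie, sigma = 2, c_threshold = 2,
                                min_area = 6L,
                                summary_method = c("mean", "sd"),
                                refine = TRUE) {
  img <- summary_image(movie, match.arg(summary_method))
  if (max(img) - min(img) < .Machine$double.eps * max(1, abs(max(img)))) {
    return(roi_map(matrix(0L, nrow(img), ncol(img)),
                   roi_table_from_pixels(img * 0L, list()), list()))
  }
  filt <- EBImage::filter2(img, log_kernel(sigma), boundary = "replicate")
  th <- mean(filt) + c_threshold * stats::sd(filt)
  seeds <- filt > th
  if (refine) {
    rng <- range(img)
    scaled <- (img - rng[1]) / (rng[2] - rng[1])
    th2 <- EBImage::otsu(scaled, range = c(0, 1))
    support <- scaled > th2
    lab <- EBImage::bwlabel(support)
    keep <- sort(unique(lab[seeds & lab > 0]))
  } else {
    lab <- EBImage::bwlabel(seeds)
    keep <- seq_len(max(lab))
  }
  pixels <- list(); labels <- matrix(0L, nrow(img), ncol(img))
  next_id <- 0L
  for (k in keep) {
    px <- which(lab == k)
    if (length(px) < min_area) next
    next_id <- next_id + 1L
    labels[px] <- next_id
    pixels[[next_id]] <- px
  }
  rois <- roi_table_from_pixels(labels, pixels)
  if (nrow(rois)) {
    rois$shape_class <- vapply(seq_len(nrow(rois)), function(k) {
      classify_roi_shape(rois[k, ])
    }, character(1))
  }
  roi_map(labels, rois, pixels)
}

#' Classify an ROI as stalk or lateral process
#'
#' Round ROIs are stalk cross-sections; elongated ones are lateral
#' processes. An ROI is a stalk iff its circularity `4*pi*A/P^2` is at
#' least `circularity_cutoff` and its best-fit-ellipse aspect ratio is at
#' most `aspect_cutoff`; otherwise it is a lateral process.
#'
#' @param roi one row of a `roi_map` ROI table (needs `area_px`,
#'   `circularity`, `aspect_ratio`), or a list with those fields.
#' @param circularity_cutoff default 0.7.
#' @param aspect_cutoff default 2.
#' @return `"stalk"` or `"lateral_process"`.
#' @export
classify_roi_shape <- function(roi, circularity_cutoff = 0.7,
                               aspect_cutoff = 2) {
  if (roi$area_px < 2L) stop("degenerate ROI: fewer than 2 pixels")
  if (roi$circularity >= circularity_cutoff &&
      roi$aspect_ratio <= aspect_cutoff) "stalk" else "lateral_process"
}

#' Fixed grid partition of the field of view
#'
#' Divides the field into `n_squares` congruent squares, each one ROI of
#' shape class `"grid"` — the partition used for recordings of the
#' neuronal glutamate sensor, where the standard 256 x 256 field is
#' divided into 16 identical squares.
#'
#' @param rows,cols field size in pixels; both must be divisible by
#'   `sqrt(n_squares)`.
#' @param n_squares a perfect square (default 16).
#' @return A [roi_map()] whose pixel sets partition the field.
#' @export
grid_roi_masks <- function(rows, cols, n_squares = 16L) {
  side <- sqrt(n_squares)
  if (side != round(side)) stop("n_squares must be a perfect square")
  side <- as.integer(side)
  if (rows %% side != 0L || cols %% side != 0L) {
    stop("field dimensions (", rows, " x ", cols,
         ") are not divisible by sqrt(n_squares) = ", side)
  }
  hr <- rows %/% side; hc <- cols %/% side
  labels <- matrix(0L, rows, cols)
  pixels <- vector("list", n_squares)
  k <- 0L
  for (i in seq_len(side)) for (j in seq_len(side)) {
    k <- k + 1L
    ys <- ((i - 1L) * hr + 1L):(i * hr)
    xs <- ((j - 1L) * hc + 1L):(j * hc)
    labels[ys, xs] <- k
    pixels[[k]] <- as.integer(outer(ys, (xs - 1L) * rows, "+"))
  }
  rois <- roi_table_from_pixels(labels, pixels,
                                rep("grid", n_squares))
  roi_map(labels, rois, pixels)
}
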