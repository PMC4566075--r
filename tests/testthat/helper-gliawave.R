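# shared fixtures and independent brute-force oracles

# compact experiment used where full 256 x 256 scale is not needed
small_config <- function(...) {
  args <- list(n_frames = 110L, field_size = c(128L, 128L),
               n_stalks = 6L, n_lateral = 6L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# --- independent oracles --------------------------------------------------

# circularity / area / perimeter straight from a logical mask, by
# scanning every pixel and its 4-neighbours
brute_shape_stats <- function(mask) {
  a <- 0L; p <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    if (!mask[y, x]) next
    a <- a + 1L
    nb_in <- (y > 1 && mask[y - 1, x]) && (y < nr && mask[y + 1, x]) &&
      (x > 1 && mask[y, x - 1]) && (x < nc && mask[y, x + 1])
    if (!nb_in) p <- p + 1L
  }
  list(area = a, perimeter = p,
       circularity = min(1, 4 * pi * a / p^2))
}

# exhaustive integer-shift search minimising the sum of squared
# differences over the overlap region
brute_best_shift <- function(ref, frame, max_shift = 6L) {
  best <- c(0L, 0L); best_err <- Inf
  nr <- nrow(ref); nc <- ncol(ref)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    err <- mean((frame[ys, xs] - ref[ys - dy, xs - dx])^2)
    if (err < best_err) { best_err <- err; best <- c(dy, dx) }
  }
  best
}

# plain run-length scan for sub-threshold excursions of a trace
brute_threshold_runs <- function(x, thr) {
  runs <- list(); start <- NA_integer_
  for (i in seq_along(x)) {
    if (x[i] < thr && is.na(start)) start <- i
    if (x[i] >= thr && !is.na(start)) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1L]] <- c(start, length(x))
  runs
}

# exhaustive scan of a derivative trace for strict k*SD upcrossings
brute_derivative_onsets <- function(dff, dt, k, smooth_width = 3L) {
  x <- smooth_trace(dff, smooth_width)
  d <- diff(x) / dt
  thr <- k * sd(d)
  which(d > thr & c(-Inf, d[-length(d)]) <= thr)
}

# overlap fraction of a detected pixel set with its best-matching truth set
best_overlap <- function(px, truth_pixel_sets) {
  max(vapply(truth_pixel_sets, function(tp) {
    length(intersect(px, tp)) / length(tp)
  }, numeric(1)))
}
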