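#' Configuration of a synthetic two-photon experiment
#'
#' Builds the parameter set for the synthetic experiment generator. The
#' generator emulates GCaMP3- or iGluSnFR-expressing Muller-cell
#' compartments in the inner plexiform layer: round stalk cross-sections
#' and elongated lateral processes, periodic retinal waves that recruit
#' each ROI with a fixed probability, slow calcium (or faster glutamate)
#' transient kinetics, compound inward EPSCs in a simultaneous
#' ganglion-cell recording, photon-like noise and slow X-Y drift.
#'
#' Sensor kinetics defaults: for `sensor = "calcium"` the transient rises
#' over 0.8 s and decays with a 1.4 s time constant, so its full width at
#' 10% of peak is about 3.9 s, inside the 3-5 s range characteristic of
#' glial GCaMP3 transients at these ages; for `sensor = "glutamate"` the
#' kinetics are faster (0.25 s rise, 0.9 s decay).
#'
#' @param n_frames number of movie frames (>= 1).
#' @param frame_rate_hz scan rate; 0.74 and 1.7 Hz are the two standard
#'   acquisition rates.
#' @param field_size `(rows, cols)` in pixels.
#' @param n_stalks,n_lateral number of round stalk ROIs (disks of radius
#'   3-5 px) and elongated lateral-process ROIs (bars, aspect >= 3).
#' @param wave_interval_mean_s,wave_interval_sd_s,wave_interval_min_s
#'   inter-wave-interval distribution: normal truncated below at the
#'   minimum. The default mean interval (40 s, about five waves in a 200 s recording) only needs to produce
#'   well-separated wave epochs.
#' @param participation_p probability in `[0, 1]` that a given ROI is
#'   recruited by a given wave. This is the central biological parameter:
#'   the packaged condition table maps experimental conditions (age,
#'   sensor, transporter block) to values of `participation_p`.
#' @param sensor `"calcium"` or `"glutamate"`; selects kinetic defaults.
#' @param transient_rise_s,transient_decay_s transient kernel rise time
#'   and decay time constant in seconds; `NULL` uses the sensor default.
#' @param peak_dff peak dF/F amplitude of one transient.
#' @param baseline_f0 resting fluorescence of ROI pixels (arbitrary
#'   units); structures expressing the indicator are visibly brighter
#'   than the surrounding neuropil.
#' @param background_f0 fluorescence of non-ROI background pixels.
#' @param noise_sd Gaussian noise SD per pixel per frame. The default
#'   gives a per-pixel signal-to-noise ratio
#'   `peak_dff * baseline_f0 / noise_sd` of about 6.
#' @param drift_px_per_frame magnitude of slow scene drift; the rendered
#'   per-frame offset is the rounded cumulative drift, so it is always an
#'   integer translation with an exact registration answer.
#' @param glial_lag_s maximum lag of a glial event onset after its wave
#'   onset; lags are uniform on `[0, glial_lag_s]`.
#' @param ephys_rate_hz sampling rate of the simulated current trace.
#'   Wave epochs are seconds long, so 1 kHz resolves them fully.
#' @param epsc_amp_pA peak amplitude of the compound EPSC (negative,
#'   inward).
#' @param epsc_rise_s,epsc_decay_s,epsc_max_dur_s EPSC envelope: linear
#'   rise, exponential decay, truncated support.
#' @param ephys_noise_sd_pA baseline current noise SD.
#' @param seed integer seed making the whole experiment reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_frames = 150L,
                              frame_rate_hz = 0.74,
                              field_size = c(256L, 256L),
                              n_stalks = 20L,
                              n_lateral = 20L,
                              wave_interval_mean_s = 40,
                              wave_interval_sd_s = 20,
                              wave_interval_min_s = 15,
                              participation_p = 0.5,
                              sensor = c("calcium", "glutamate"),
                              transient_rise_s = NULL,
                              transient_decay_s = NULL,
                              peak_dff = 0.5,
                              baseline_f0 = 1000,
                              background_f0 = 200,
                              noise_sd = 80,
                              drift_px_per_frame = 0.02,
                              glial_lag_s = 3,
                              ephys_rate_hz = 1000,
                              epsc_amp_pA = -100,
                              epsc_rise_s = 0.3,
                              epsc_decay_s = 1.2,
                              epsc_max_dur_s = 4,
                              ephys_noise_sd_pA = 4,
                              seed = 1L) {
  sensor <- match.arg(sensor)
  if (is.null(transient_rise_s)) {
    transient_rise_s <- if (sensor == "calcium") 0.8 else 0.25
  }
  if (is.null(transient_decay_s)) {
    transient_decay_s <- if (sensor == "calcium") 1.4 else 0.9
  }
  cfg <- list(
    n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
    field_size = as.integer(field_size), n_stalks = as.integer(n_stalks),
    n_lateral = as.integer(n_lateral),
    wave_interval_mean_s = wave_interval_mean_s,
    wave_interval_sd_s = wave_interval_sd_s,
    wave_interval_min_s = wave_interval_min_s,
    participation_p = participation_p, sensor = sensor,
    transient_rise_s = transient_rise_s,
    transient_decay_s = transient_decay_s,
    peak_dff = peak_dff, baseline_f0 = baseline_f0,
    background_f0 = background_f0, noise_sd = noise_sd,
    drift_px_per_frame = drift_px_per_frame, glial_lag_s = glial_lag_s,
    ephys_rate_hz = ephys_rate_hz, epsc_amp_pA = epsc_amp_pA,
    epsc_rise_s = epsc_rise_s, epsc_decay_s = epsc_decay_s,
    epsc_max_dur_s = epsc_max_dur_s,
    ephys_noise_sd_pA = ephys_noise_sd_pA, seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  if (cfg$frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (cfg$participation_p < 0 || cfg$participation_p > 1) {
    stop("participation_p must lie in [0, 1]")
  }
  if (cfg$baseline_f0 <= 0) stop("baseline_f0 must be positive")
  if (cfg$wave_interval_min_s <= 0) stop("wave_interval_min_s must be > 0")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("simulation_config: %d frames at %.3g Hz, %d x %d px, ",
           "%d stalks + %d processes, sensor %s, participation_p %.2f, ",
           "seed %d\n"),
    x$n_frames, x$frame_rate_hz, x$field_size[1], x$field_size[2],
    x$n_stalks, x$n_lateral, x$sensor, x$participation_p, x$seed
  ))
  invisible(x)
}

# rasterise a disk of radius r (pixel-centre test with half-pixel slack,
# which keeps small disks round rather than diamond-shaped)
disk_mask_offsets <- function(r) {
  s <- ceiling(r)
  g <- expand.grid(dy = -s:s, dx = -s:s)
  g[g$dy^2 + g$dx^2 <= (r + 0.5)^2, , drop = FALSE]
}

# rasterise a bar of given length/width rotated by theta
bar_mask_offsets <- function(len, wid, theta) {
  s <- ceiling(len / 2) + 1L
  g <- expand.grid(dy = -s:s, dx = -s:s)
  u <- g$dx * cos(theta) + g$dy * sin(theta)
  v <- -g$dx * sin(theta) + g$dy * cos(theta)
  g[abs(u) <= len / 2 & abs(v) <= wid / 2, , drop = FALSE]
}

#' Generate a synthetic ROI layout
#'
#' Places `n_stalks` round ROIs (disks, radius 3-5 px) and `n_lateral`
#' elongated ROIs (bars, aspect ratio >= 3, random orientation) on the
#' field without overlap and with a guard margin between shapes, mimicking
#' stalk cross-sections and lateral processes of Muller cells in the IPL.
#'
#' @param config a [simulation_config()].
#' @param rng_seed integer seed; defaults to `config$seed`.
#' @param margin_px minimum Chebyshev gap enforced between ROIs.
#' @return A [roi_map()] whose `shape_class` column records the true
#'   class of each placed shape.
#' @export
make_layout <- function(config, rng_seed = config$seed, margin_px = 3L) {
  set.seed(rng_seed)
  rows <- config$field_size[1]; cols <- config$field_size[2]
  labels <- matrix(0L, rows, cols)
  blocked <- matrix(FALSE, rows, cols)  # ROI pixels dilated by margin
  pixels <- list(); class_v <- character(0)
  ntot <- config$n_stalks + config$n_lateral
  border <- 8L  # keep shapes clear of edges so drift cannot clip them
  for (k in seq_len(ntot)) {
    is_stalk <- k <= config$n_stalks
    placed <- FALSE
    for (try in 1:300) {
      off <- if (is_stalk) {
        disk_mask_offsets(stats::runif(1, 3, 5))
      } else {
        len <- stats::runif(1, 12, 20)
        wid <- stats::runif(1, 2.6, 3.4)
        bar_mask_offsets(len, wid, stats::runif(1, 0, pi))
      }
      ext <- max(abs(c(off$dy, off$dx)))
      cy <- sample.int(rows - 2L * (border + ext), 1L) + border + ext
      cx <- sample.int(cols - 2L * (border + ext), 1L) + border + ext
      ry <- cy + off$dy; rx <- cx + off$dx
      idx <- (rx - 1L) * rows + ry
      if (any(blocked[idx])) next
      labels[idx] <- k
      pixels[[k]] <- sort(idx)
      class_v[k] <- if (is_stalk) "stalk" else "lateral_process"
      # block the shape plus margin for subsequent placements
      for (dy in -margin_px:margin_px) for (dx in -margin_px:margin_px) {
        yy <- pmin(pmax(ry + dy, 1L), rows)
        xx <- pmin(pmax(rx + dx, 1L), cols)
        blocked[(xx - 1L) * rows + yy] <- TRUE
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ROI ", k,
           ": field too crowded for the requested layout")
    }
  }
  rois <- roi_table_from_pixels(labels, pixels, class_v)
  roi_map(labels, rois, pixels)
}

#' Simulate wave timing and ROI recruitment
#'
#' Draws wave onsets from the configured truncated-normal inter-wave
#' distribution and recruits each ROI independently per wave with
#' probability `participation_p`. Each recruited ROI receives exactly one
#' event onset lagged uniformly in `[0, glial_lag_s]` after the wave
#' onset. Waves are only kept if the lagged event window fits inside the
#' recording, so every ground-truth event lies inside the recording
#' interval.
#'
#' @param config a [simulation_config()].
#' @param n_rois number of ROIs in the layout (defaults to the config's
#'   stalk + process count).
#' @param rng_seed integer seed; defaults to `config$seed`.
#' @return A [ground_truth()] object. The wave list may be empty if the
#'   recording is shorter than the first drawn interval.
#' @export
simulate_waves <- function(config, n_rois = config$n_stalks + config$n_lateral,
                           rng_seed = config$seed) {
  set.seed(rng_seed)
  duration <- config$n_frames / config$frame_rate_hz
  # latest onset such that onset + lag + rise is still observable
  last_ok <- duration - config$glial_lag_s - config$transient_rise_s
  onsets <- numeric(0)
  t <- rtruncnorm1(config$wave_interval_mean_s, config$wave_interval_sd_s,
                   config$wave_interval_min_s)
  while (t <= last_ok) {
    onsets <- c(onsets, t)
    t <- t + rtruncnorm1(config$wave_interval_mean_s,
                         config$wave_interval_sd_s,
                         config$wave_interval_min_s)
  }
  recruited <- vector("list", length(onsets))
  event_onsets <- stats::setNames(
    rep(list(numeric(0)), n_rois), as.character(seq_len(n_rois))
  )
  for (w in seq_along(onsets)) {
    ids <- which(stats::runif(n_rois) < config$participation_p)
    recruited[[w]] <- ids
    if (length(ids)) {
      lags <- stats::runif(length(ids), 0, config$glial_lag_s)
      for (j in seq_along(ids)) {
        id <- as.character(ids[j])
        event_onsets[[id]] <- c(event_onsets[[id]], onsets[w] + lags[j])
      }
    }
  }
  ground_truth(onsets, recruited, event_onsets, n_rois)
}

# one draw from a normal truncated below at `lo` (inverse-CDF method)
rtruncnorm1 <- function(mean, sd, lo) {
  if (sd <= 0) return(max(mean, lo))
  u <- stats::runif(1, stats::pnorm((lo - mean) / sd), 1)
  mean + sd * stats::qnorm(u)
}

#' Fluorescence transient kernel
#'
#' Unit-peak transient shape used by the simulator: linear rise over
#' `rise_s`, then exponential decay with time constant `decay_s`.
#'
#' @param t_s time since event onset (seconds); values < 0 give 0.
#' @param rise_s rise time to peak.
#' @param decay_s decay time constant.
#' @return Kernel values in `[0, 1]`.
#' @export
transient_kernel <- function(t_s, rise_s, decay_s) {
  k <- numeric(length(t_s))
  up <- t_s >= 0 & t_s < rise_s
  dn <- t_s >= rise_s
  k[up] <- t_s[up] / rise_s
  k[dn] <- exp(-(t_s[dn] - rise_s) / decay_s)
  k
}

#' Render the fluorescence movie
#'
#' Renders the synthetic movie from a layout and ground truth. ROI pixels
#' rest at `baseline_f0` and follow
#' `baseline_f0 * (1 + sum of event kernels)` when events occur;
#' background pixels sit at the dimmer `background_f0`. Gaussian noise of
#' SD `noise_sd` is added per pixel per frame, and the whole scene is
#' translated by the rounded cumulative drift (an integer offset per
#' frame, recorded in the returned truth when requested).
#'
#' @param layout a [roi_map()] from [make_layout()].
#' @param truth a [ground_truth()] from [simulate_waves()].
#' @param config a [simulation_config()].
#' @param rng_seed seed for noise and drift direction; defaults to
#'   `config$seed`.
#' @return A list with elements `movie` (a [movie_stack()]) and
#'   `frame_shifts` (integer `frames x 2` matrix of applied (dy, dx)).
#' @export
render_movie <- function(layout, truth, config, rng_seed = config$seed) {
  set.seed(rng_seed)
  rows <- config$field_size[1]; cols <- config$field_size[2]
  nf <- config$n_frames
  npx <- rows * cols
  tt <- (seq_len(nf) - 1L) / config$frame_rate_hz
  base <- matrix(config$background_f0, rows, cols)
  for (px in layout$pixels) base[px] <- config$baseline_f0
  data <- array(rep(base, nf), dim = c(rows, cols, nf))
  # add event kernels per ROI
  for (r in seq_len(nrow(layout$rois))) {
    id <- layout$rois$id[r]
    ons <- truth$event_onsets[[as.character(id)]]
    if (is.null(ons) || !length(ons)) next
    s <- numeric(nf)
    for (o in ons) {
      s <- s + transient_kernel(tt - o, config$transient_rise_s,
                                config$transient_decay_s)
    }
    s <- s * config$peak_dff * config$baseline_f0
    px <- layout$pixels[[r]]
    active <- which(s > 0)
    if (length(active)) {
      idx <- rep(px, times = length(active)) +
        rep((active - 1L) * npx, each = length(px))
      data[idx] <- data[idx] + rep(s[active], each = length(px))
    }
  }
  # slow drift: rounded cumulative offset, random fixed direction
  theta <- stats::runif(1, 0, 2 * pi)
  shifts <- cbind(
    dy = as.integer(round(config$drift_px_per_frame * (seq_len(nf) - 1L) *
                            sin(theta))),
    dx = as.integer(round(config$drift_px_per_frame * (seq_len(nf) - 1L) *
                            cos(theta)))
  )
  if (any(shifts != 0L)) {
    for (f in seq_len(nf)) {
      if (any(shifts[f, ] != 0L)) {
        data[, , f] <- translate_frame(data[, , f], shifts[f, 1], shifts[f, 2],
                                       fill = config$background_f0)
      }
    }
  }
  if (config$noise_sd > 0) {
    data <- data + stats::rnorm(length(data), sd = config$noise_sd)
    data[data < 0] <- 0
  }
  list(movie = movie_stack(data, config$frame_rate_hz),
       frame_shifts = shifts)
}

#' Simulate the ganglion-cell current trace
#'
#' Produces a voltage-clamp current trace with baseline near 0 pA and one
#' compound inward EPSC envelope per wave: linear rise over `epsc_rise_s`
#' to `epsc_amp_pA` (negative), exponential decay with time constant
#' `epsc_decay_s`, truncated at `epsc_max_dur_s`.
#'
#' @param truth a [ground_truth()] holding the wave onsets.
#' @param config a [simulation_config()].
#' @param rng_seed seed for the baseline noise; defaults to
#'   `config$seed`.
#' @return An [ephys_trace()] spanning the movie duration.
#' @export
simulate_ephys <- function(truth, config, rng_seed = config$seed) {
  set.seed(rng_seed)
  duration <- config$n_frames / config$frame_rate_hz
  dt <- 1 / config$ephys_rate_hz
  time_s <- seq(0, duration, by = dt)
  cur <- stats::rnorm(length(time_s), sd = config$ephys_noise_sd_pA)
  for (o in truth$wave_onsets_s) {
    rel <- time_s - o
    in_ep <- rel >= 0 & rel <= config$epsc_max_dur_s
    if (!any(in_ep)) next
    env <- transient_kernel(rel[in_ep], config$epsc_rise_s,
                            config$epsc_decay_s)
    cur[in_ep] <- cur[in_ep] + config$epsc_amp_pA * env
  }
  ephys_trace(time_s, cur, config$ephys_rate_hz)
}

#' Generate a complete synthetic experiment
#'
#' Composes [make_layout()], [simulate_waves()], [render_movie()] and
#' [simulate_ephys()] with sub-seeds derived deterministically from
#' `config$seed`, so the same config always produces bit-identical
#' outputs. Movie and current trace share the time origin `t = 0`.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `movie` ([movie_stack()]), `ephys`
#'   ([ephys_trace()]), `layout` ([roi_map()]) and `truth`
#'   ([ground_truth()]; its `frame_shifts` element records the rendered
#'   drift).
#' @export
generate_experiment <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4L)
  layout <- make_layout(config, rng_seed = sub[1])
  truth <- simulate_waves(config, n_rois = nrow(layout$rois),
                          rng_seed = sub[2])
  rend <- render_movie(layout, truth, config, rng_seed = sub[3])
  truth$frame_shifts <- rend$frame_shifts
  ephys <- simulate_ephys(truth, config, rng_seed = sub[4])
  list(movie = rend$movie, ephys = ephys, layout = layout, truth = truth)
}

#' Packaged experimental condition table
#'
#' Reads the condition table shipped with the package (or a user file of
#' the same YAML layout): a mapping from condition name to
#' [simulation_config()] overrides. The packaged entries encode the
#' recruitment probabilities of the experimental groups the pipeline is
#' validated against (age P7/P9/P11, calcium vs glutamate sensor, and
#' glutamate-transporter block with DL-TBOA, which raises
#' `participation_p`).
#'
#' @param path YAML file; default is the packaged table.
#' @return Named list of override lists.
#' @export
load_conditions <- function(path = system.file("extdata", "conditions.yaml",
                                               package = "gliawave")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("condition table not found: ", path)
  }
  yaml::read_yaml(path)
}

#' Build a simulation config for a named condition
#'
#' @param condition condition name present in the table, e.g.
#'   `"P7_control"` or `"P11_TBOA"`.
#' @param ... further overrides passed to [simulation_config()] (for
#'   example `seed` or `n_frames`), taking precedence over the table.
#' @param table a condition table from [load_conditions()].
#' @return A [simulation_config()].
#' @export
condition_config <- function(condition, ..., table = load_conditions()) {
  if (!condition %in% names(table)) {
    stop("unknown condition '", condition, "'; available: ",
         paste(names(table), collapse = ", "))
  }
  overrides <- table[[condition]]
  overrides$reported_mean_pct <- NULL
  overrides$reported_sd_pct <- NULL
  dots <- list(...)
  overrides[names(dots)] <- dots
  do.call(simulation_config, overrides)
}
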