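test_that("layout placement honours counts, disjointness and empty case", {
  cfg0 <- simulation_config(n_stalks = 0L, n_lateral = 0L)
  empty <- make_layout(cfg0)
  expect_equal(nrow(empty$rois), 0L)
  expect_true(all(empty$labels == 0L))

  cfg <- simulation_config(n_stalks = 10L, n_lateral = 10L, seed = 1L)
  lay <- make_layout(cfg)
  expect_equal(nrow(lay$rois), 20L)
  all_px <- unlist(lay$pixels)
  expect_equal(anyDuplicated(all_px), 0L)
  expect_equal(sum(lay$labels > 0L), length(all_px))
  expect_setequal(lay$rois$shape_class[1:10], "stalk")
  expect_setequal(lay$rois$shape_class[11:20], "lateral_process")
})

test_that("generated stalks and processes separate on brute-force circularity", {
  cfg <- simulation_config(n_stalks = 8L, n_lateral = 8L, seed = 7L)
  lay <- make_layout(cfg)
  for (k in seq_len(nrow(lay$rois))) {
    mask <- lay$labels == lay$rois$id[k]
    bs <- brute_shape_stats(mask)
    expect_equal(bs$area, lay$rois$area_px[k])
    expect_equal(bs$circularity, lay$rois$circularity[k], tolerance = 1e-12)
    if (lay$rois$shape_class[k] == "stalk") {
      expect_gte(bs$circularity, 0.7)
    } else {
      # elongated shapes fail the stalk rule on circularity or aspect
      expect_true(bs$circularity < 0.7 || lay$rois$aspect_ratio[k] > 2)
    }
  }
})

test_that("overcrowded field errors out of placement retries", {
  cfg <- simulation_config(field_size = c(40L, 40L),
                           n_stalks = 30L, n_lateral = 10L)
  expect_error(make_layout(cfg), "crowded")
})

test_that("wave recruitment respects participation_p limits and binomial mean", {
  cfg1 <- small_config(participation_p = 1, seed = 2L)
  gt1 <- simulate_waves(cfg1, n_rois = 12L)
  expect_true(length(gt1$wave_onsets_s) >= 1L)
  for (r in gt1$recruited) expect_setequal(r, 1:12)
  expect_equal(gt1$true_participation_per_wave,
               rep(1, length(gt1$wave_onsets_s)))

  cfg0 <- small_config(participation_p = 0, seed = 2L)
  gt0 <- simulate_waves(cfg0, n_rois = 12L)
  expect_true(all(lengths(gt0$recruited) == 0L))

  # long recording: ~200 waves, 40 ROIs; binomial closed form for the SE
  cfgh <- simulation_config(n_frames = 6000L, participation_p = 0.5,
                            seed = 11L)
  gth <- simulate_waves(cfgh, n_rois = 40L)
  n_w <- length(gth$wave_onsets_s)
  expect_gt(n_w, 150L)
  se <- sqrt(0.5 * 0.5 / (40 * n_w))
  expect_lt(abs(mean(gth$true_participation_per_wave) - 0.5), 3 * se)
})

test_that("every recruited ROI gets exactly one lagged event onset", {
  cfg <- small_config(participation_p = 0.6, seed = 5L)
  gt <- simulate_waves(cfg, n_rois = 12L)
  for (w in seq_along(gt$wave_onsets_s)) {
    for (id in gt$recruited[[w]]) {
      ons <- gt$event_onsets[[as.character(id)]]
      in_lag <- ons >= gt$wave_onsets_s[w] &
        ons <= gt$wave_onsets_s[w] + cfg$glial_lag_s
      expect_equal(sum(in_lag), 1L)
    }
  }
  expect_equal(sum(lengths(gt$event_onsets)), sum(lengths(gt$recruited)))
})

test_that("noiseless renders have exact baselines and kernel peaks", {
  cfg <- small_config(noise_sd = 0, drift_px_per_frame = 0,
                      participation_p = 0, seed = 3L)
  lay <- make_layout(cfg)
  gt <- simulate_waves(cfg, n_rois = nrow(lay$rois))
  mv <- render_movie(lay, gt, cfg)$movie
  # no events: every frame identical, ROI pixels at baseline_f0
  expect_true(all(mv$data[, , 1] == mv$data[, , n_frames(mv)]))
  for (px in lay$pixels) {
    expect_equal(mean(mv$data[, , 1][px]), cfg$baseline_f0)
  }
  expect_equal(mv$data[1, 1, 1], cfg$background_f0)

  # single event: max ROI-mean dF/F equals the kernel maximum at frame times
  gt1 <- gt
  gt1$event_onsets[["1"]] <- 30
  mv1 <- render_movie(lay, gt1, cfg)$movie
  tr <- mv1$data
  roi_mean <- vapply(seq_len(dim(tr)[3]), function(f) {
    mean(tr[, , f][lay$pixels[[1]]])
  }, numeric(1))
  dff <- (roi_mean - cfg$baseline_f0) / cfg$baseline_f0
  expected_peak <- cfg$peak_dff * max(transient_kernel(
    frame_times(mv1) - 30, cfg$transient_rise_s, cfg$transient_decay_s
  ))
  expect_equal(max(dff), expected_peak, tolerance = 1e-10)
})

test_that("default calcium kernel has a 3-5 s width at 10% of peak", {
  cfg <- simulation_config(sensor = "calcium")
  tt <- seq(0, 20, by = 0.001)
  k <- transient_kernel(tt, cfg$transient_rise_s, cfg$transient_decay_s)
  width <- diff(range(tt[k >= 0.1 * max(k)]))
  expect_gte(width, 3)
  expect_lte(width, 5)
  # glutamate kinetics are faster
  cfg_g <- simulation_config(sensor = "glutamate")
  kg <- transient_kernel(tt, cfg_g$transient_rise_s, cfg_g$transient_decay_s)
  expect_lt(diff(range(tt[kg >= 0.1 * max(kg)])), width)
})

test_that("simulated current traces carry one inward EPSC per wave", {
  cfg <- small_config(seed = 4L)
  # no waves: baseline only
  gt0 <- ground_truth(numeric(0), list(), list(), 12L)
  tr0 <- simulate_ephys(gt0, cfg)
  se <- cfg$ephys_noise_sd_pA / sqrt(length(tr0$current_pA))
  expect_lt(abs(mean(tr0$current_pA)), 3 * se)

  # two noiseless waves: exactly two sub-baseline excursions at 10 and 60 s
  cfg0 <- small_config(ephys_noise_sd_pA = 0)
  gt2 <- ground_truth(c(10, 60), list(integer(0), integer(0)), list(), 12L)
  tr2 <- simulate_ephys(gt2, cfg0)
  runs <- brute_threshold_runs(tr2$current_pA, -1)
  expect_length(runs, 2L)
  onsets <- vapply(runs, function(r) tr2$time_s[r[1]], numeric(1))
  expect_equal(onsets, c(10, 60), tolerance = 0.05)
  expect_lt(min(tr2$current_pA), 0)
  expect_equal(min(tr2$current_pA), cfg0$epsc_amp_pA, tolerance = 0.5)
})

test_that("generate_experiment is seed-deterministic and self-consistent", {
  cfg <- small_config(seed = 9L)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$movie$data, e2$movie$data)
  expect_identical(e1$ephys$current_pA, e2$ephys$current_pA)
  expect_identical(e1$truth$wave_onsets_s, e2$truth$wave_onsets_s)

  # duration arithmetic and shared time axis
  dur <- cfg$n_frames / cfg$frame_rate_hz
  expect_equal(max(frame_times(e1$movie)), dur - 1 / cfg$frame_rate_hz)
  expect_gte(max(e1$ephys$time_s), max(frame_times(e1$movie)))

  # bookkeeping: total events match recruitment; all events in-recording
  expect_equal(sum(lengths(e1$truth$event_onsets)),
               sum(lengths(e1$truth$recruited)))
  all_ev <- unlist(e1$truth$event_onsets)
  if (length(all_ev)) {
    expect_true(all(all_ev >= 0 & all_ev <= dur))
  }
})

test_that("expected recruitment is monotone in participation_p", {
  mean_recruited <- function(p) {
    mean(vapply(1:6, function(s) {
      cfg <- small_config(participation_p = p, seed = s)
      gt <- simulate_waves(cfg, n_rois = 30L)
      if (!length(gt$recruited)) return(NA_real_)
      mean(lengths(gt$recruited))
    }, numeric(1)), na.rm = TRUE)
  }
  ms <- vapply(c(0.1, 0.4, 0.7, 1.0), mean_recruited, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("condition table carries the studied groups and builds configs", {
  tab <- load_conditions()
  expect_setequal(
    names(tab),
    c("P7_control", "P9_control", "P11_control", "P11_TBOA",
      "P9_iGluSnFR", "P11_iGluSnFR")
  )
  cfg <- condition_config("P11_TBOA", seed = 2L)
  expect_equal(cfg$participation_p, 0.61)
  expect_equal(cfg$sensor, "calcium")
  cfg_g <- condition_config("P9_iGluSnFR", seed = 2L)
  expect_equal(cfg_g$sensor, "glutamate")
  expect_equal(cfg_g$frame_rate_hz, 1.7)
  expect_error(condition_config("P5_control"), "unknown condition")
})
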