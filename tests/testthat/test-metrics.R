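waves_df <- function(onsets, offsets) {
  data.frame(onset_s = onsets, offset_s = offsets,
             peak_current_pA = rep(-100, length(onsets)),
             charge_pC = rep(100, length(onsets)))
}

events_df <- function(roi_id, onset_s) {
  n <- length(onset_s)
  data.frame(roi_id = roi_id, onset_s = onset_s, peak_s = onset_s + 1,
             offset_s = onset_s + 3, peak_dff = rep(0.3, n),
             duration_s = rep(3, n))
}

test_that("per-wave participation counts responsive ROIs correctly", {
  waves <- waves_df(c(10, 50), c(13, 53))
  # every ROI responds to every wave -> 100%
  ev <- events_df(rep(1:5, 2), rep(c(11, 51), each = 5))
  p <- responsive_per_wave(ev, waves, 5)
  expect_equal(p$per_wave_pct, c(100, 100))
  expect_equal(p$mean_pct, 100)

  # no events -> 0%
  p0 <- responsive_per_wave(events_df(integer(0), numeric(0)), waves, 5)
  expect_equal(p0$per_wave_pct, c(0, 0))

  # 3 of 10 ROIs respond during the only wave -> 30%
  ev3 <- events_df(c(1, 5, 9), c(11, 12, 12.5))
  p3 <- responsive_per_wave(ev3, waves_df(10, 13), 10)
  expect_equal(p3$per_wave_pct, 30)

  expect_error(responsive_per_wave(ev3, waves_df(10, 13), 0), "ROI")
  expect_error(responsive_per_wave(ev3, waves_df(numeric(0), numeric(0)), 5),
               "wave")
})

test_that("events outside the coincidence window never count", {
  waves <- waves_df(100, 104)
  # default window [98, 109]: only the 98.5 s event falls inside
  ev <- events_df(c(1, 2, 3), c(97.5, 98.5, 109.4))
  p <- responsive_per_wave(ev, waves, 10)
  expect_equal(p$per_wave_pct, 10)
})

test_that("any-wave participation is the union over waves", {
  waves <- waves_df(c(10, 50), c(13, 53))
  # disjoint halves respond to waves 1 and 2
  ev <- events_df(c(1, 2, 3, 4), c(11, 11, 51, 51))
  expect_equal(responsive_any_wave(ev, waves, 4), 100)
  p <- responsive_per_wave(ev, waves, 4)
  expect_equal(p$per_wave_pct, c(50, 50))
  expect_error(responsive_any_wave(ev, waves_df(numeric(0), numeric(0)), 4),
               "wave")
})

test_that("any-wave participation dominates per-wave on random cases", {
  set.seed(44)
  for (i in 1:20) {
    n_w <- sample(1:4, 1)
    onsets <- sort(runif(n_w, 0, 150))
    waves <- waves_df(onsets, onsets + 3)
    n_ev <- sample(0:30, 1)
    ev <- events_df(sample(1:15, n_ev, replace = TRUE), runif(n_ev, 0, 160))
    p <- responsive_per_wave(ev, waves, 15)
    expect_gte(responsive_any_wave(ev, waves, 15) + 1e-12,
               max(p$per_wave_pct))
  }
})

test_that("participation is invariant under ROI relabelling", {
  waves <- waves_df(c(10, 50), c(13, 53))
  ev <- events_df(c(1, 2, 7), c(11, 12, 51))
  perm <- c(9, 4, 1, 2, 3, 5, 6, 8, 7, 10)
  ev2 <- ev; ev2$roi_id <- perm[ev$roi_id]
  p1 <- responsive_per_wave(ev, waves, 10)
  p2 <- responsive_per_wave(ev2, waves, 10)
  expect_equal(p1$per_wave_pct, p2$per_wave_pct)
})

test_that("participation time-course bins event onsets", {
  tc0 <- participation_timecourse(events_df(integer(0), numeric(0)), 20, 10)
  expect_true(all(tc0$pct_responsive == 0))

  ev <- events_df(1:20, rep(25, 20))
  tc <- participation_timecourse(ev, 20, 10, t_range = c(0, 50))
  expect_equal(tc$pct_responsive[tc$t_start_s == 20], 100)
  expect_equal(sum(tc$pct_responsive > 0), 1L)

  # counts sum to total events when no ROI fires twice per bin
  set.seed(45)
  ev2 <- events_df(sample(1:50, 30, replace = FALSE), runif(30, 0, 100))
  tc2 <- participation_timecourse(ev2, 50, 5, t_range = c(0, 100))
  expect_equal(sum(tc2$pct_responsive / 100 * 50), 30)
})

test_that("inter-transient intervals pool within-ROI onset differences", {
  ev <- events_df(c(1, 1, 1), c(0, 10, 20))
  iti <- inter_transient_intervals(ev)
  expect_equal(sort(iti$intervals_s), c(10, 10))

  # one event per ROI contributes nothing
  ev1 <- events_df(1:5, c(3, 8, 20, 44, 60))
  expect_length(inter_transient_intervals(ev1)$intervals_s, 0L)

  set.seed(46)
  evr <- events_df(sample(1:6, 40, replace = TRUE), runif(40, 0, 500))
  cdf <- inter_transient_intervals(evr)$cdf
  expect_true(all(diff(cdf$cum_prob) >= 0))
  expect_equal(cdf$cum_prob[nrow(cdf)], 1)
  expect_true(all(cdf$interval_s > 0))
})

test_that("higher wave frequency shifts the ITI distribution left", {
  med_iti <- function(interval_mean) {
    pooled <- numeric(0)
    for (s in 1:6) {
      cfg <- small_config(n_frames = 400L,
                          wave_interval_mean_s = interval_mean,
                          wave_interval_sd_s = 5,
                          participation_p = 0.9, seed = 600L + s)
      gt <- simulate_waves(cfg, n_rois = 20L)
      ev <- events_df(
        rep(seq_len(20), times = vapply(as.character(1:20), function(id) {
          length(gt$event_onsets[[id]])
        }, integer(1))),
        unlist(gt$event_onsets[as.character(1:20)])
      )
      pooled <- c(pooled, inter_transient_intervals(ev)$intervals_s)
    }
    median(pooled)
  }
  expect_lt(med_iti(25), med_iti(60))
})

test_that("evoked averages collapse identical responses and average peaks", {
  t_s <- seq(0, 99, by = 1)
  resp <- rep(0, 100)
  resp[c(11:15, 41:45, 71:75)] <- c(0.2, 0.6, 1.0, 0.5, 0.1)
  tr <- dff_traces(1:2, t_s, cbind(resp * 100 + 100, rep(100, 100)),
                   frame_rate_hz = 1)
  tr <- compute_dff(tr, f0_method = "external", f0 = c(100, 100))
  wins <- focal_stim_epochs(stim_protocol(c(10, 40, 70)), window_s = 9)
  av <- evoked_response_average(tr, wins)
  # roi 1 responds identically every application; roi 2 never
  expect_equal(unname(av$roi_peak_dff), c(1.0, 0.0))
  expect_equal(mean(av$roi_peak_dff), 0.5)
  expect_equal(max(av$mean_dff), 0.5)
  # identical segments within each ROI: the SD envelope reflects only
  # the across-ROI spread
  expect_equal(max(av$sd_dff), sd(c(1, 0)))
  expect_error(
    evoked_response_average(tr, focal_stim_epochs(stim_protocol(95))),
    "exceeds"
  )
})

test_that("group comparisons pick the right test and post-hoc table", {
  x <- c(1.1, 1.3, 0.9, 1.2)
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 4))
  expect_gt(same$p_value, 0.99)

  set.seed(47)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 5, 1)
  sep <- compare_groups(c(a, b), rep(c("a", "b"), each = 20))
  expect_lt(sep$p_value, 1e-3)

  g3 <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 4))
  lab <- rep(c("g1", "g2", "g3"), each = 8)
  tuk <- compare_groups(g3, lab, method = "anova_tukey")
  expect_equal(nrow(tuk$posthoc), 3L)
  kd <- compare_groups(g3, lab, method = "kruskal_dunn")
  expect_equal(nrow(kd$posthoc), 3L)
  expect_lt(kd$p_value, 0.01)
  # the extreme pair is the strongest post-hoc contrast
  expect_lt(kd$posthoc$p_adjusted[kd$posthoc$comparison == "g1 - g3"],
            min(kd$posthoc$p_adjusted) + 1e-12)

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("Dunn z statistics match the closed form on a tiny example", {
  vals <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  grp <- rep(c("a", "b", "c"), each = 3)
  dn <- gliawave:::dunn_posthoc(vals, grp)
  # mean ranks 2, 5, 8; no ties: var_base = n(n+1)/12 = 7.5
  z_ab <- (2 - 5) / sqrt(7.5 * (2 / 3))
  expect_equal(dn$z[dn$comparison == "a - b"], z_ab)
  expect_equal(dn$z[dn$comparison == "a - c"], 2 * z_ab)
})
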