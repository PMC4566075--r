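# assign each event to at most one wave: the wave whose extended window
# [onset - pre_s, offset + post_s] contains the event onset; among
# several candidates, the wave with the nearest onset wins
assign_events_to_waves <- function(events, waves, pre_s = 2, post_s = 5) {
  if (!nrow(events)) return(integer(0))
  vapply(events$onset_s, function(o) {
    ok <- which(o >= waves$onset_s - pre_s & o <= waves$offset_s + post_s)
    if (!length(ok)) return(NA_integer_)
    ok[which.min(abs(waves$onset_s[ok] - o))]
  }, integer(1))
}

#' Percent responsive ROIs per wave
#'
#' For each wave, the percentage of ROIs with at least one detected
#' event onset inside the wave's coincidence window
#' `[onset - pre_s, offset + post_s]`. The default margins (2 s before,
#' 5 s after) cover the lag of glial events behind the neuronal wave
#' onset plus the one-frame onset-timing uncertainty of detection at the
#' slowest standard scan rate. Each event is assigned to at most one
#' wave (nearest onset).
#'
#' @param events event data.frame from [detect_transients()].
#' @param waves wave-epoch data.frame from [detect_wave_epochs()] (needs
#'   `onset_s`, `offset_s`); at least one wave is required.
#' @param rois a [roi_map()] or the total ROI count (> 0).
#' @param pre_s,post_s coincidence window margins in seconds.
#' @param condition optional condition label carried into the summary.
#' @return A list of class `participation_summary`: `per_wave_pct`,
#'   `mean_pct`, `sd_pct`, `n_rois`, `n_waves`, `condition`.
#' @export
responsive_per_wave <- function(events, waves, rois, pre_s = 2, post_s = 5,
                                condition = NA_character_) {
  nr <- n_rois(rois)
  if (nr < 1L) stop("participation requires at least one ROI")
  if (!nrow(waves)) stop("participation requires at least one wave")
  wv <- assign_events_to_waves(events, waves, pre_s, post_s)
  per_wave <- vapply(seq_len(nrow(waves)), function(w) {
    100 * length(unique(events$roi_id[!is.na(wv) & wv == w])) / nr
  }, numeric(1))
  structure(
    list(per_wave_pct = per_wave, mean_pct = mean(per_wave),
         sd_pct = stats::sd(per_wave), n_rois = nr,
         n_waves = nrow(waves), condition = condition),
    class = "participation_summary"
  )
}

#' @export
print.participation_summary <- function(x, ...) {
  cat(sprintf(
    "participation: %.1f +/- %.1f%% responsive ROIs per wave (%d ROIs, %d waves%s)\n",
    x$mean_pct, if (is.na(x$sd_pct)) 0 else x$sd_pct, x$n_rois, x$n_waves,
    if (is.na(x$condition)) "" else paste0(", ", x$condition)
  ))
  invisible(x)
}

#' Percent of ROIs responsive during at least one wave
#'
#' As [responsive_per_wave()], but an ROI counts once if it responds in
#' any wave; always at least the maximum per-wave percentage.
#'
#' @inheritParams responsive_per_wave
#' @return A single percentage in `[0, 100]`.
#' @export
responsive_any_wave <- function(events, waves, rois, pre_s = 2, post_s = 5) {
  nr <- n_rois(rois)
  if (nr < 1L) stop("participation requires at least one ROI")
  if (!nrow(waves)) stop("participation requires at least one wave")
  wv <- assign_events_to_waves(events, waves, pre_s, post_s)
  100 * length(unique(events$roi_id[!is.na(wv)])) / nr
}

#' Participation time-course
#'
#' Histogram over time of the percentage of ROIs with an event onset in
#' each bin, the quantity displayed under simultaneous imaging/recording
#' traces.
#'
#' @param events event data.frame.
#' @param rois a [roi_map()] or ROI count.
#' @param bin_s bin width in seconds (> 0).
#' @param t_range `(start, end)` of the axis; defaults to `(0, max
#'   offset)`.
#' @return data.frame `t_start_s`, `t_end_s`, `pct_responsive`.
#' @export
participation_timecourse <- function(events, rois, bin_s,
                                     t_range = NULL) {
  if (bin_s <= 0) stop("bin_s must be positive")
  nr <- n_rois(rois)
  if (is.null(t_range)) {
    t_range <- c(0, if (nrow(events)) max(events$offset_s) else bin_s)
  }
  breaks <- seq(t_range[1], t_range[2] + bin_s, by = bin_s)
  pct <- vapply(seq_len(length(breaks) - 1L), function(b) {
    inb <- events$onset_s >= breaks[b] & events$onset_s < breaks[b + 1L]
    100 * length(unique(events$roi_id[inb])) / nr
  }, numeric(1))
  data.frame(t_start_s = breaks[-length(breaks)],
             t_end_s = breaks[-1], pct_responsive = pct)
}

#' Inter-transient-interval distribution
#'
#' Successive event-onset differences within each ROI, pooled across
#' ROIs, with their empirical cumulative distribution. ROIs with fewer
#' than two events contribute nothing.
#'
#' @param events event data.frame (onsets need not be pre-sorted).
#' @return A list of class `iti_distribution`: `intervals_s` (pooled)
#'   and `cdf` (data.frame `interval_s`, `cum_prob`, non-decreasing and
#'   ending at 1).
#' @export
inter_transient_intervals <- function(events) {
  ivs <- unlist(lapply(split(events$onset_s, events$roi_id), function(o) {
    if (length(o) < 2L) numeric(0) else diff(sort(o))
  }), use.names = FALSE)
  if (length(ivs)) {
    s <- sort(ivs)
    cdf <- data.frame(interval_s = s,
                      cum_prob = seq_along(s) / length(s))
  } else {
    cdf <- data.frame(interval_s = numeric(0), cum_prob = numeric(0))
  }
  structure(list(intervals_s = ivs, cdf = cdf),
            class = "iti_distribution")
}

#' @export
print.iti_distribution <- function(x, ...) {
  cat(sprintf("iti_distribution: %d intervals, median %.1f s\n",
              length(x$intervals_s),
              if (length(x$intervals_s)) stats::median(x$intervals_s)
              else NA_real_))
  invisible(x)
}

#' Evoked-response average over focal applications
#'
#' Aligns dF/F segments to each application onset, averages them across
#' applications per ROI, and reports the grand mean and SD envelope
#' across ROIs together with each ROI's peak evoked amplitude (the
#' quantity compared across drug conditions).
#'
#' @param traces a [dff_traces()] with `dff` computed.
#' @param stim_windows data.frame from [focal_stim_epochs()].
#' @return A list of class `evoked_average`: `t_rel_s` (times relative
#'   to application onset), `mean_dff`, `sd_dff`, `roi_peak_dff` (named
#'   by ROI id), `n_applications`.
#' @export
evoked_response_average <- function(traces, stim_windows) {
  if (is.null(traces$dff)) stop("run compute_dff() first")
  if (!nrow(stim_windows)) stop("no stimulation windows supplied")
  t_s <- traces$t_s
  seg_idx <- lapply(seq_len(nrow(stim_windows)), function(i) {
    idx <- which(t_s >= stim_windows$start_s[i] &
                   t_s <= stim_windows$end_s[i])
    if (!length(idx) || stim_windows$end_s[i] > max(t_s) + 1e-9 ||
        stim_windows$start_s[i] < min(t_s) - 1e-9) {
      stop("stimulation window [", stim_windows$start_s[i], ", ",
           stim_windows$end_s[i], "] s exceeds the recording")
    }
    idx
  })
  m <- min(lengths(seg_idx))
  seg_idx <- lapply(seg_idx, function(i) i[seq_len(m)])
  # per-ROI mean across applications: frames x rois
  per_roi <- Reduce(`+`, lapply(seg_idx, function(i) {
    traces$dff[i, , drop = FALSE]
  })) / length(seg_idx)
  peaks <- apply(per_roi, 2, max)
  names(peaks) <- traces$roi_ids
  structure(
    list(
      t_rel_s = t_s[seg_idx[[1]]] - stim_windows$start_s[1],
      mean_dff = rowMeans(per_roi),
      sd_dff = apply(per_roi, 1, stats::sd),
      roi_peak_dff = peaks,
      n_applications = nrow(stim_windows)
    ),
    class = "evoked_average"
  )
}

# Dunn's rank-based post-hoc comparisons after a Kruskal-Wallis test,
# with the standard tie correction; p-values Holm-adjusted
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  mr <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  z <- apply(pairs, 2, function(p) {
    (mr[p[1]] - mr[p[2]]) /
      sqrt(var_base * (1 / ns[p[1]] + 1 / ns[p[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    comparison = paste(pairs[1, ], pairs[2, ], sep = " - "),
    z = as.numeric(z),
    p_value = as.numeric(p),
    p_adjusted = stats::p.adjust(p, method = p_adjust)
  )
}

#' Compare groups of measurements
#'
#' Two groups are compared with a two-sided t test; more than two with a
#' one-way ANOVA followed by Tukey's post-hoc test, or with a
#' Kruskal-Wallis test followed by Dunn's post-hoc comparisons. The
#' significance level convention is 0.05.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length as `values`; at least 2
#'   groups with at least 2 observations each.
#' @param method `"auto"` (t test for 2 groups, ANOVA + Tukey
#'   otherwise), `"ttest"`, `"anova_tukey"` or `"kruskal_dunn"`.
#' @return A list of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, and for more than two groups a `posthoc` data.frame.
#' @export
compare_groups <- function(values, groups,
                           method = c("auto", "ttest", "anova_tukey",
                                      "kruskal_dunn")) {
  method <- match.arg(method)
  groups <- factor(groups)
  ns <- table(groups)
  if (length(ns) < 2L || any(ns < 2L)) {
    stop("need at least 2 groups with at least 2 observations each")
  }
  if (method == "auto") {
    method <- if (length(ns) == 2L) "ttest" else "anova_tukey"
  }
  if (method == "ttest") {
    if (length(ns) != 2L) stop("t test requires exactly 2 groups")
    ht <- stats::t.test(values ~ groups)
    res <- list(method = "Welch two-sample t-test",
                statistic = unname(ht$statistic), p_value = ht$p.value,
                posthoc = NULL)
  } else if (method == "anova_tukey") {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    res <- list(
      method = "one-way ANOVA with Tukey post-hoc",
      statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
      posthoc = data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p_adjusted = tk[, "p adj"], row.names = NULL
      )
    )
  } else {
    kw <- stats::kruskal.test(values, groups)
    res <- list(
      method = "Kruskal-Wallis with Dunn post-hoc",
      statistic = unname(kw$statistic), p_value = kw$p.value,
      posthoc = dunn_posthoc(values, groups)
    )
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3g, p = %.3g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}
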