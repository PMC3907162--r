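#' Detect saccades in an eye trace
#'
#' Velocity-threshold detector: radial eye velocity (from sample-to-sample
#' displacement) is smoothed with a short boxcar; a saccade onset is an
#' upward crossing of `v_thresh` and the offset the following downward
#' crossing. Events below the minimum amplitude are discarded. Amplitude
#' and direction come from the positions at onset and offset. Defaults
#' (30 deg/s threshold, 5 ms boxcar) are standard oculomotor practice.
#'
#' @param gaze a [gaze_stream()] in degrees at a uniform rate.
#' @param v_thresh velocity threshold in degrees/s.
#' @param min_amp minimum amplitude in degrees.
#' @param smooth_ms boxcar width in ms.
#' @return data.frame of class `saccade_events`: `t_onset_us`,
#'   `t_offset_us`, `amplitude` (degrees), `angle` (degrees, 0 rightward,
#'   counterclockwise positive).
#' @export
detect_saccades <- function(gaze, v_thresh = 30, min_amp = 0.5,
                            smooth_ms = 5) {
  if (nrow(gaze) < 3)
    return(empty_saccades())
  dt_s <- diff(gaze$t_us[1:2]) / 1e6
  vx <- c(0, diff(gaze$x)) / dt_s
  vy <- c(0, diff(gaze$y)) / dt_s
  v <- sqrt(vx^2 + vy^2)
  k <- max(1L, round(smooth_ms / (dt_s * 1000)))
  if (k > 1) v <- stats::filter(v, rep(1 / k, k), sides = 2)
  v[is.na(v)] <- 0
  fast <- v > v_thresh
  starts <- which(fast & !c(FALSE, fast[-length(fast)]))
  ends <- which(!fast & c(FALSE, fast[-length(fast)]))
  if (length(ends) && length(starts) && ends[1] < starts[1])
    ends <- ends[-1]
  n <- min(length(starts), length(ends))
  if (n == 0) return(empty_saccades())
  starts <- starts[seq_len(n)]; ends <- ends[seq_len(n)]
  dx <- gaze$x[ends] - gaze$x[starts]
  dy <- gaze$y[ends] - gaze$y[starts]
  amp <- sqrt(dx^2 + dy^2)
  keep <- amp >= min_amp
  structure(data.frame(t_onset_us = gaze$t_us[starts][keep],
                       t_offset_us = gaze$t_us[ends][keep],
                       amplitude = amp[keep],
                       angle = atan2(dy[keep], dx[keep]) * 180 / pi),
            class = c("saccade_events", "data.frame"))
}

empty_saccades <- function() {
  structure(data.frame(t_onset_us = numeric(0), t_offset_us = numeric(0),
                       amplitude = numeric(0), angle = numeric(0)),
            class = c("saccade_events", "data.frame"))
}

#' Build an event-aligned raster and PSTH
#'
#' Peristimulus time histogram: spike counts in fixed-width bins relative
#' to each alignment event, pooled over trials, with the per-trial aligned
#' spike times preserved as raster rows. The rate scale is
#' `counts / (n_trials * bin_width)` in spikes/s. The conventional 10 ms
#' bin width is the default.
#'
#' @param spike_trains either a single numeric vector of spike times
#'   (microseconds, one continuous train aligned to multiple events) or a
#'   list with one train per trial (then `align_us` must match its length).
#' @param align_us alignment-event times (microseconds); at least one.
#' @param bin_ms bin width in ms.
#' @param window_ms `c(pre, post)` window around the event in ms (pre
#'   negative).
#' @return object of class `psth`: `counts`, `edges_ms`, `centers_ms`,
#'   `rate_hz`, `n_trials`, `bin_ms`, `raster` (list of per-trial aligned
#'   spike times in ms).
#' @export
build_psth <- function(spike_trains, align_us, bin_ms = 10,
                       window_ms = c(-100, 300)) {
  if (length(align_us) < 1) stop("at least one alignment event is required")
  per_trial <- is.list(spike_trains)
  if (per_trial && length(spike_trains) != length(align_us))
    stop("per-trial spike trains must match the number of alignment events")
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  raster <- vector("list", length(align_us))
  for (i in seq_along(align_us)) {
    st <- if (per_trial) spike_trains[[i]] else spike_trains
    rel <- (st - align_us[i]) / 1000
    raster[[i]] <- rel[rel >= window_ms[1] & rel <= window_ms[2]]
  }
  all_rel <- unlist(raster)
  # right-open bins [lo, hi); the last edge is exclusive like the others
  counts <- if (length(all_rel))
    tabulate(findInterval(all_rel, edges,
                          rightmost.closed = FALSE, all.inside = FALSE),
             nbins = length(edges))[seq_len(length(edges) - 1L)]
  else rep(0L, length(edges) - 1L)
  n_tr <- length(align_us)
  structure(list(counts = counts, edges_ms = edges,
                 centers_ms = edges[-length(edges)] + bin_ms / 2,
                 rate_hz = counts / (n_tr * bin_ms / 1000),
                 n_trials = n_tr, bin_ms = bin_ms, raster = raster),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d trials, %d bins of %g ms, %d aligned spikes\n",
              x$n_trials, length(x$counts), x$bin_ms, sum(x$counts)))
  invisible(x)
}

#' Plot a raster and PSTH
#'
#' @param x a [build_psth()] object.
#' @param main title.
#' @param ... passed to `barplot`.
#' @export
plot.psth <- function(x, main = "Raster / PSTH", ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = range(x$edges_ms), ylim = c(0, x$n_trials + 1),
                 xlab = "", ylab = "trial", main = main)
  for (i in seq_along(x$raster))
    if (length(x$raster[[i]]))
      graphics::points(x$raster[[i]], rep(i, length(x$raster[[i]])),
                       pch = "|", cex = 0.4)
  graphics::abline(v = 0, lty = 3)
  graphics::plot(x$centers_ms, x$rate_hz, type = "s", xlab = "time (ms)",
                 ylab = "rate (spikes/s)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Spike-density function
#'
#' Each trial's aligned spike train is convolved with a unit-area Gaussian
#' kernel and the result averaged across trials, scaled to spikes/s. The
#' integral over the window equals the mean aligned spike count per trial
#' (up to kernel mass outside the window for spikes near the edges).
#'
#' @inheritParams build_psth
#' @param sd_ms Gaussian kernel SD in ms (> 0).
#' @param dt_ms waveform sampling interval in ms.
#' @return object of class `spike_density`: `t_ms`, `rate_hz`, `sd_ms`,
#'   `n_trials`.
#' @export
spike_density <- function(spike_trains, align_us, sd_ms = 10,
                          window_ms = c(-100, 300), dt_ms = 1) {
  if (sd_ms <= 0) stop("sd_ms must be > 0")
  if (length(align_us) < 1) stop("at least one alignment event is required")
  per_trial <- is.list(spike_trains)
  t_ms <- seq(window_ms[1], window_ms[2], by = dt_ms)
  acc <- numeric(length(t_ms))
  for (i in seq_along(align_us)) {
    st <- if (per_trial) spike_trains[[i]] else spike_trains
    rel <- (st - align_us[i]) / 1000
    rel <- rel[rel >= window_ms[1] - 4 * sd_ms & rel <= window_ms[2] + 4 * sd_ms]
    for (s in rel)
      acc <- acc + stats::dnorm(t_ms, mean = s, sd = sd_ms)
  }
  # dnorm is per-ms density; x1000 converts to spikes/s
  structure(list(t_ms = t_ms, rate_hz = acc / length(align_us) * 1000,
                 sd_ms = sd_ms, n_trials = length(align_us)),
            class = "spike_density")
}

#' @export
print.spike_density <- function(x, ...) {
  cat(sprintf("<spike_density> %d trials, kernel SD %g ms, peak %.1f sp/s\n",
              x$n_trials, x$sd_ms, max(x$rate_hz)))
  invisible(x)
}

#' @export
plot.spike_density <- function(x, ...) {
  graphics::plot(x$t_ms, x$rate_hz, type = "l", xlab = "time (ms)",
                 ylab = "rate (spikes/s)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' First-peak response latency from a PSTH
#'
#' Latency of the earliest post-event bin whose rate exceeds the baseline
#' mean plus `criterion_sd` baseline standard deviations, refined below bin
#' width by a local parabolic fit through the crossing bin and its
#' neighbors. A PSTH with no bin above criterion yields a "no response"
#' result (`NA`), which is distinct from a latency of 0.
#'
#' @param psth a [build_psth()] object.
#' @param baseline_ms `c(lo, hi)` baseline window (must precede the event).
#' @param criterion_sd threshold in baseline SDs above the baseline mean.
#' @return latency in ms (numeric), or `NA` with attribute
#'   `no_response = TRUE`.
#' @export
first_peak_latency <- function(psth, baseline_ms = c(-100, 0),
                               criterion_sd = 3) {
  stopifnot(inherits(psth, "psth"))
  if (baseline_ms[2] > 0) stop("baseline window must precede the event")
  base_idx <- psth$centers_ms >= baseline_ms[1] &
    psth$centers_ms <= baseline_ms[2]
  if (!any(base_idx)) stop("baseline window contains no bins")
  mu <- mean(psth$rate_hz[base_idx])
  sdv <- stats::sd(psth$rate_hz[base_idx])
  if (!is.finite(sdv) || sdv == 0) sdv <- sqrt(max(mu, 1)) # Poisson floor
  thresh <- mu + criterion_sd * sdv
  post <- which(psth$centers_ms > 0 & psth$rate_hz > thresh)
  if (!length(post))
    return(structure(NA_real_, no_response = TRUE))
  i <- post[1]
  lat <- psth$centers_ms[i]
  # sub-bin refinement: a local parabola through bins (i-1, i, i+1) models
  # the rising edge; the latency is where it crosses the half-rise level
  # (midway between baseline mean and the local response peak), bounded to
  # the span between the previous bin center and the crossing-bin center
  if (i > 1 && i < length(psth$rate_hz)) {
    xs <- psth$centers_ms[(i - 1):(i + 1)]
    ys <- psth$rate_hz[(i - 1):(i + 1)]
    half <- (mu + max(ys[2:3])) / 2
    co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
    cross <- NULL
    if (!is.null(co) && co[3] != 0) {
      disc <- co[2]^2 - 4 * co[3] * (co[1] - half)
      if (is.finite(disc) && disc >= 0) {
        roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
        cand <- roots[roots >= xs[1] & roots <= xs[2]]
        if (length(cand)) cross <- min(cand)
      }
    }
    if (is.null(cross) && ys[2] > ys[1])     # degenerate fit: linear edge
      cross <- xs[1] + (half - ys[1]) / (ys[2] - ys[1]) * psth$bin_ms
    if (!is.null(cross))
      lat <- max(lat - psth$bin_ms, min(lat, cross))
  }
  lat
}

#' Preferred saccade vector of a perisaccadic neuron
#'
#' Bins saccades by amplitude and direction, computes the mean firing rate
#' in a burst window around each saccade onset, and estimates the preferred
#' vector as the rate-weighted circular mean direction and rate-weighted
#' mean amplitude over the supra-median bins of the resulting heat map.
#' A neuron whose rate does not depend on direction produces a flat map;
#' the direction estimate is then flagged unreliable (weighted resultant
#' length below `reliability_min`).
#'
#' @param spike_train spike times (microseconds, one continuous train).
#' @param saccades a [detect_saccades()] data.frame (or compatible) with at
#'   least 20 rows spanning at least 90 degrees of directions.
#' @param burst_ms `c(lo, hi)` window around saccade onset (ms).
#' @param n_angle,n_amp number of direction and amplitude bins.
#' @param reliability_min minimum weighted resultant length for a reliable
#'   direction estimate.
#' @return object of class `preferred_vector`: `amplitude`, `angle`
#'   (degrees), `reliable`, `resultant`, `map` (amp x angle rate matrix),
#'   `angle_centers`, `amp_centers`.
#' @export
preferred_vector <- function(spike_train, saccades, burst_ms = c(0, 20),
                             n_angle = 8, n_amp = 4,
                             reliability_min = 0.1) {
  if (nrow(saccades) < 20)
    stop("insufficient directional coverage: need at least 20 saccades")
  ang <- saccades$angle %% 360
  span <- diff(range(ang))
  if (span < 90)
    stop("insufficient directional coverage: directions span < 90 degrees")
  if (length(spike_train) == 0) stop("insufficient activity: zero spikes")
  dur_s <- (burst_ms[2] - burst_ms[1]) / 1000
  rate <- vapply(seq_len(nrow(saccades)), function(i) {
    t0 <- saccades$t_onset_us[i]
    sum(spike_train >= t0 + burst_ms[1] * 1000 &
        spike_train < t0 + burst_ms[2] * 1000) / dur_s
  }, numeric(1))
  ang_edges <- seq(0, 360, length.out = n_angle + 1)
  amp_edges <- seq(min(saccades$amplitude), max(saccades$amplitude),
                   length.out = n_amp + 1)
  ai <- pmin(findInterval(ang, ang_edges, rightmost.closed = TRUE), n_angle)
  mi <- pmin(findInterval(saccades$amplitude, amp_edges,
                          rightmost.closed = TRUE), n_amp)
  map <- matrix(NA_real_, n_amp, n_angle)
  for (a in seq_len(n_amp)) for (b in seq_len(n_angle)) {
    sel <- mi == a & ai == b
    if (any(sel)) map[a, b] <- mean(rate[sel])
  }
  ang_centers <- ang_edges[-length(ang_edges)] + diff(ang_edges) / 2
  amp_centers <- amp_edges[-length(amp_edges)] + diff(amp_edges) / 2
  med <- stats::median(map, na.rm = TRUE)
  supra <- which(!is.na(map) & map > med, arr.ind = TRUE)
  if (nrow(supra) == 0) supra <- which(!is.na(map), arr.ind = TRUE)
  w <- map[supra]
  th <- ang_centers[supra[, 2]] * pi / 180
  C <- sum(w * cos(th)); S <- sum(w * sin(th))
  pref_angle <- (atan2(S, C) * 180 / pi) %% 360
  pref_amp <- sum(w * amp_centers[supra[, 1]]) / sum(w)
  # reliability from the full map: a direction-independent neuron has
  # near-equal weight in every direction, so the rate-weighted resultant
  # over all bins vanishes; supra-median selection alone would bias it up
  all_idx <- which(!is.na(map), arr.ind = TRUE)
  wa <- map[all_idx]
  tha <- ang_centers[all_idx[, 2]] * pi / 180
  resultant <- sqrt(sum(wa * cos(tha))^2 + sum(wa * sin(tha))^2) / sum(wa)
  structure(list(amplitude = pref_amp, angle = pref_angle,
                 reliable = resultant >= reliability_min,
                 resultant = resultant, map = map,
                 angle_centers = ang_centers, amp_centers = amp_centers),
            class = "preferred_vector")
}

#' @export
print.preferred_vector <- function(x, ...) {
  cat(sprintf("<preferred_vector> %.1f deg amplitude at %.0f deg angle (%s)\n",
              x$amplitude, x$angle,
              if (x$reliable) "reliable"
              else sprintf("unreliable, resultant %.2f", x$resultant)))
  invisible(x)
}

#' @export
plot.preferred_vector <- function(x, ...) {
  graphics::image(x$angle_centers, x$amp_centers, t(x$map),
                  xlab = "direction (deg)", ylab = "amplitude (deg)",
                  main = "Perisaccadic rate map", ...)
  graphics::points(x$angle, x$amplitude, pch = 8, cex = 2)
  invisible(x)
}

#' Write a PSTH to CSV
#'
#' @param psth a [build_psth()] object.
#' @param path output CSV.
#' @export
write_psth_csv <- function(psth, path) {
  utils::write.csv(data.frame(center_ms = psth$centers_ms,
                              count = psth$counts, rate_hz = psth$rate_hz),
                   path, row.names = FALSE)
  invisible(path)
}
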