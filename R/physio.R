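# Hemodynamic and sympathetic-nerve signal processing: cerebral perfusion
# pressure, MAP and heart rate from the arterial waveform, rectified and
# exponentially smoothed nerve activity normalized between resting (100%)
# and post-blockade floor (0%), and stimulus-to-response timing.

#' Cerebral perfusion pressure
#'
#' `CPP = MAP - ICP`, elementwise. When a central venous pressure trace is
#' supplied the subtrahend is `max(ICP, CVP)` per sample; by default CVP is
#' ignored, matching the operative definition CPP = MAP - ICP.
#'
#' @param map_trace mean arterial pressure, mmHg.
#' @param icp_trace intracranial pressure, mmHg (same length).
#' @param cvp optional central venous pressure, mmHg.
#' @return CPP trace, mmHg.
#' @export
compute_cpp <- function(map_trace, icp_trace, cvp = NULL) {
  if (length(map_trace) != length(icp_trace))
    abort_field("icp_trace", "must have the same length as map_trace")
  sub <- icp_trace
  if (!is.null(cvp)) {
    if (length(cvp) != length(icp_trace))
      abort_field("cvp", "must have the same length as icp_trace")
    sub <- pmax(icp_trace, cvp)
  }
  map_trace - sub
}

#' MAP and heart rate from the arterial pressure waveform
#'
#' MAP is a sliding-window mean (default 2 s) of the waveform. Heart rate
#' is 60 / interbeat interval from detected systolic peaks (local maxima
#' above the sliding mean, with a refractory period of 0.25 x the median
#' interbeat interval), linearly interpolated onto the full time axis. A
#' pulseless waveform yields `NA` heart rate with a warning.
#'
#' @param abp arterial pressure waveform, mmHg.
#' @param sample_rate Hz (>= 50 recommended to resolve pulses).
#' @param map_window MAP averaging window, seconds.
#' @return list: `map` (mmHg), `hr` (bpm, `NA` if pulseless), `beat_times`
#'   (s).
#' @export
map_and_hr <- function(abp, sample_rate, map_window = 2) {
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  n <- length(abp)
  w <- max(1L, round(map_window * sample_rate))
  map_tr <- as.numeric(stats::filter(abp, rep(1 / w, w), sides = 2))
  # edge fill: shrink the window near the borders
  na_idx <- which(is.na(map_tr))
  for (i in na_idx) {
    a <- max(1, i - w %/% 2); b <- min(n, i + w %/% 2)
    map_tr[i] <- mean(abp[a:b])
  }
  pulse <- abp - map_tr
  amp <- stats::quantile(abs(pulse), 0.95, names = FALSE)
  if (amp < 1e-6 || stats::sd(pulse) < 1e-8) {
    warning("pulseless waveform: heart rate undefined")
    return(list(map = map_tr, hr = rep(NA_real_, n), beat_times = numeric(0)))
  }
  # low-pass the pulse (~20 ms) so measurement noise does not create
  # spurious local maxima, then detect systolic peaks above half the pulse
  # amplitude with a refractory period of 0.25 x the median interbeat
  # interval (bootstrapped from a first high-threshold pass)
  pulse_s <- smooth_trace(pulse, sigma = max(1, 0.02 * sample_rate))
  find_peaks <- function(thr, refractory) {
    up <- pulse_s > thr
    lm <- which(up & c(-Inf, pulse_s[-n]) < pulse_s &
                  pulse_s >= c(pulse_s[-1], -Inf))
    if (length(lm) < 3 || refractory < 1) return(lm)
    peaks <- integer(0); last <- -1e9
    for (i in lm) {
      if (i - last > refractory) { peaks <- c(peaks, i); last <- i }
      else if (pulse_s[i] > pulse_s[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i; last <- i
      }
    }
    peaks
  }
  first <- find_peaks(0.5 * amp, 0)
  if (length(first) < 3) {
    warning("too few pulses detected: heart rate undefined")
    return(list(map = map_tr, hr = rep(NA_real_, n), beat_times = numeric(0)))
  }
  ibi0 <- stats::median(diff(first))
  peaks <- find_peaks(0.25 * amp, max(1, round(0.25 * ibi0)))
  bt <- (peaks - 1) / sample_rate
  ibi <- diff(bt)
  hr_at <- (bt[-1] + bt[-length(bt)]) / 2
  hr <- stats::approx(hr_at, 60 / ibi, xout = (seq_len(n) - 1) / sample_rate,
                      rule = 2)$y
  # interbeat jitter makes the instantaneous rate noisy; report it smoothed
  # over the same window as MAP
  hr_s <- as.numeric(stats::filter(hr, rep(1 / w, w), sides = 2))
  for (i in which(is.na(hr_s))) {
    a <- max(1, i - w %/% 2); b <- min(n, i + w %/% 2)
    hr_s[i] <- mean(hr[a:b])
  }
  list(map = map_tr, hr = hr_s, beat_times = bt)
}

#' Rectify and smooth raw sympathetic nerve activity
#'
#' First-order exponential smoothing of the full-wave rectified signal
#' with time constant `tau` (default 100 ms): the integrated nerve
#' activity.
#'
#' @param rsna_raw raw nerve signal, volts.
#' @param sample_rate Hz.
#' @param tau smoothing time constant, seconds (> 0).
#' @return smoothed rectified trace.
#' @export
rectify_smooth_rsna <- function(rsna_raw, sample_rate, tau = 0.1) {
  check_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  a <- exp(-1 / (sample_rate * tau))
  x <- abs(rsna_raw)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive",
                           init = x[1]))
}

#' Normalize smoothed nerve activity to percent of resting
#'
#' Affine map taking the post-blockade floor to 0% and the resting level
#' to 100%.
#'
#' @param smoothed smoothed rectified trace.
#' @param resting_level resting activity level (same units), must exceed
#'   `blockade_floor`.
#' @param blockade_floor activity after ganglionic blockade.
#' @return percent trace.
#' @export
normalize_rsna <- function(smoothed, resting_level, blockade_floor = 0) {
  if (!is.finite(resting_level) || resting_level <= blockade_floor)
    abort_field("resting_level", "must exceed blockade_floor")
  100 * (smoothed - blockade_floor) / (resting_level - blockade_floor)
}

#' Stimulus protocol
#'
#' @param onset,offset stimulus start and end, seconds (`offset > onset`).
#' @param target_delta_icp intended ICP step, mmHg (metadata).
#' @return a `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(onset, offset, target_delta_icp = NA_real_) {
  check_scalar(onset, "onset", lower = 0)
  if (offset <= onset) abort_field("offset", "must be > onset")
  structure(list(onset = onset, offset = offset,
                 target_delta_icp = target_delta_icp),
            class = "stimulus_protocol")
}

#' Stimulus-to-response delay
#'
#' Onset rule: the first time after stimulus onset at which the response
#' exceeds `baseline mean + k * baseline sd` for at least `m` consecutive
#' samples; the delay is that time minus the stimulus onset. Returns `NA`
#' with a warning when no sustained crossing occurs before
#' `offset + search_beyond`.
#'
#' @param time time axis, seconds.
#' @param response response trace (e.g. MAP).
#' @param protocol a [stimulus_protocol()].
#' @param k threshold in baseline SDs (default 2).
#' @param m required consecutive samples (default 5). For heavily smoothed
#'   responses (e.g. sliding-mean MAP) choose `m` to span at least the
#'   smoothing window, otherwise autocorrelated baseline ripples count as
#'   sustained crossings.
#' @param min_delta absolute floor (response units) on the threshold
#'   offset above the baseline mean (default 0 = pure SD rule).
#' @param search_beyond seconds beyond offset to search (default 60).
#' @return delay in seconds, or `NA`.
#' @export
response_delay <- function(time, response, protocol, k = 2, m = 5,
                           min_delta = 0, search_beyond = 60) {
  base_idx <- time < protocol$onset
  if (!any(base_idx)) abort_field("protocol", "no samples before onset")
  mu <- mean(response[base_idx]); s <- stats::sd(response[base_idx])
  if (!is.finite(s)) s <- 0
  thr <- mu + max(k * s, min_delta)
  search <- which(time >= protocol$onset &
                    time <= protocol$offset + search_beyond)
  above <- response[search] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= m)
  if (length(hit) == 0) {
    warning("no sustained response crossing found")
    return(NA_real_)
  }
  time[search[starts[hit[1]]]] - protocol$onset
}

#' Summarize the physiological response to a stimulus
#'
#' Epoch-mean differences (stimulus minus an equal-length pre-onset
#' baseline) for MAP, HR and normalized RSNA, the response delay of MAP,
#' and the persistence: time after offset until the response first returns
#' to (and stays within, for `m` samples) baseline mean + 1 baseline SD.
#' Peak changes (stimulus-epoch maximum minus baseline mean) are also
#' reported.
#'
#' @param rec a [physio_recording()].
#' @param protocol a [stimulus_protocol()].
#' @param resting_window seconds at the start of the recording used as the
#'   RSNA resting reference (default: up to stimulus onset).
#' @param k onset-rule threshold in baseline SDs; the sustained-crossing
#'   run is set to the MAP averaging window (2 s) and the threshold floor
#'   to `min_delta` mmHg, see [response_delay()].
#' @param min_delta absolute onset threshold floor, mmHg (default 1).
#' @param max_persistence longest persistence searched, seconds.
#' @return list of class `physio_response`: `delta_map`, `delta_hr`,
#'   `delta_rsna` (% of resting), `peak_map`, `peak_hr`, `response_delay`,
#'   `persistence`, plus the derived `map`, `hr`, `cpp`, `rsna_pct` traces.
#' @export
response_summary <- function(rec, protocol, resting_window = NULL,
                             k = 2, min_delta = 1, max_persistence = Inf) {
  m <- max(5, round(2 * rec$sample_rate))   # sustain >= the MAP window
  t <- rec$time
  mh <- map_and_hr(rec$abp, rec$sample_rate)
  cpp <- compute_cpp(mh$map, rec$icp)
  sm <- rectify_smooth_rsna(rec$rsna_raw, rec$sample_rate)
  rest_idx <- if (is.null(resting_window)) t < protocol$onset
              else t < resting_window
  resting <- mean(sm[rest_idx])
  rsna_pct <- if (resting > 0) normalize_rsna(sm, resting, 0)
              else rep(NA_real_, length(sm))

  len <- protocol$offset - protocol$onset
  base_idx <- t >= protocol$onset - len & t < protocol$onset
  stim_idx <- t >= protocol$onset & t < protocol$offset
  epoch_delta <- function(x) mean(x[stim_idx]) - mean(x[base_idx])
  epoch_peak <- function(x) max(x[stim_idx]) - mean(x[base_idx])

  delay <- response_delay(t, mh$map, protocol, k = k, m = m,
                          min_delta = min_delta)

  # persistence of the MAP response beyond stimulus offset
  mu <- mean(mh$map[base_idx]); s <- stats::sd(mh$map[base_idx])
  post_idx <- which(t >= protocol$offset &
                      t <= protocol$offset + max_persistence)
  below <- mh$map[post_idx] <= mu + s
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= m)
  persistence <- if (length(ok) == 0) NA_real_
                 else t[post_idx[starts[ok[1]]]] - protocol$offset

  structure(list(
    delta_map = epoch_delta(mh$map),
    delta_hr = if (all(is.na(mh$hr))) NA_real_ else epoch_delta(mh$hr),
    delta_rsna = if (all(is.na(rsna_pct))) NA_real_ else epoch_delta(rsna_pct),
    peak_map = epoch_peak(mh$map),
    peak_hr = if (all(is.na(mh$hr))) NA_real_ else epoch_peak(mh$hr),
    response_delay = delay, persistence = persistence,
    map = mh$map, hr = mh$hr, cpp = cpp, rsna_pct = rsna_pct),
    class = "physio_response")
}

#' @export
print.physio_response <- function(x, ...) {
  cat(sprintf(paste0("<physio_response> dMAP = %.1f mmHg, dHR = %.1f bpm, ",
                     "dRSNA = %.1f%%, delay = %.1f s, persistence = %.0f s\n"),
              x$delta_map, x$delta_hr, x$delta_rsna, x$response_delay,
              x$persistence))
  invisible(x)
}
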