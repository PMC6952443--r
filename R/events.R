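# Per-ROI event statistics: active time (% of time the Ca2+ signal is
# elevated), event frequency and duration per epoch, responder
# classification, and peristimulus averages aligned to stimulus onset or
# offset.

#' Event intervals from a binary activity vector
#'
#' Maximal runs of `TRUE`, as half-open frame intervals `[start, end)`,
#' discarding runs shorter than `min_duration` frames.
#'
#' @param activity logical vector.
#' @param frame_interval seconds per frame (stored as an attribute for
#'   duration computations).
#' @param min_duration minimum run length in frames (default 2, suppressing
#'   single-frame threshold crossings).
#' @return integer matrix with columns `start`, `end` (half-open, 1-based)
#'   and attribute `frame_interval`.
#' @export
intervals_from_mask <- function(activity, frame_interval = 1,
                                min_duration = 2) {
  iv <- runs_to_intervals(as.logical(activity))
  iv <- iv[iv[, 2] - iv[, 1] >= min_duration, , drop = FALSE]
  attr(iv, "frame_interval") <- frame_interval
  iv
}

#' Refine detected event intervals to half-prominence extent
#'
#' Detection marks every frame above the significance threshold (2 noise
#' SDs of the denoised trace), which spans the full tail of a transient.
#' For duration and active-time measurements each detected interval is
#' refined to the contiguous frames where the (detrended) trace stays at or
#' above `fraction` of the event's peak — full width at half maximum by
#' default. Refined intervals never extend beyond the detected ones.
#'
#' @param trace the denoised trace the mask came from.
#' @param intervals interval matrix from [intervals_from_mask()].
#' @param fraction of the event peak defining the extent (default 0.5).
#' @param detrend_window running-median detrend window (frames; 0 = none),
#'   matched to the detection settings.
#' @return interval matrix of the same shape contract.
#' @export
refine_intervals <- function(trace, intervals, fraction = 0.5,
                             detrend_window = 31) {
  if (is.null(intervals) || nrow(intervals) == 0) return(intervals)
  x <- trace
  if (detrend_window > 0 && length(x) > 3) {
    wk <- min(2L * (detrend_window %/% 2L) + 1L,
              2L * ((length(x) - 1L) %/% 2L) + 1L)
    x <- x - stats::runmed(x, wk, endrule = "median")
  }
  fi <- attr(intervals, "frame_interval")
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  for (k in seq_len(nrow(intervals))) {
    a <- intervals[k, 1]; b <- intervals[k, 2] - 1L
    seg <- x[a:b]
    # greedy multi-peak extraction: events merged into one detected run are
    # split wherever the trace dips below `fraction` of a peak
    thr_global <- fraction * max(seg)
    unassigned <- rep(TRUE, length(seg))
    repeat {
      cand <- which(unassigned & seg >= thr_global)
      if (length(cand) == 0) break
      pk <- cand[which.max(seg[cand])]
      thr <- fraction * seg[pk]
      lo <- pk; while (lo > 1 && seg[lo - 1] >= thr && unassigned[lo - 1])
        lo <- lo - 1
      hi <- pk; while (hi < length(seg) && seg[hi + 1] >= thr &&
                       unassigned[hi + 1]) hi <- hi + 1
      out <- rbind(out, c(a + lo - 1L, a + hi))
      unassigned[lo:hi] <- FALSE
    }
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("start", "end")
  attr(out, "frame_interval") <- fi
  out
}

#' Active time of a set of intervals
#'
#' `100 * total active frames / n_frames`, for disjoint half-open
#' intervals.
#'
#' @param intervals matrix with `start`, `end` columns (half-open).
#' @param n_frames total frame count (> 0).
#' @return percent in `[0, 100]`.
#' @export
active_time <- function(intervals, n_frames) {
  check_scalar(n_frames, "n_frames", lower = 1, integerish = TRUE)
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  covered <- sum(pmin(intervals[, 2], n_frames + 1L) -
                   pmax(intervals[, 1], 1L))
  100 * covered / n_frames
}

#' Event statistics within an epoch
#'
#' Frequency counts events whose start frame lies inside the epoch, per
#' minute of epoch duration; mean duration is over those events; active
#' time is restricted to the epoch.
#'
#' @param intervals interval matrix from [intervals_from_mask()].
#' @param epoch integer vector `c(first_frame, last_frame)` (inclusive).
#' @param frame_interval seconds per frame.
#' @param label optional epoch label (`"baseline"`, `"stimulus"`, ...).
#' @return data frame: `epoch`, `active_time` (%), `frequency`
#'   (events/min), `mean_duration` (s; `NA` when no events), `n_events`.
#' @export
event_stats <- function(intervals, epoch, frame_interval = 1,
                        label = NA_character_) {
  if (length(epoch) != 2L || epoch[2] < epoch[1])
    abort_field("epoch", "must be c(first_frame, last_frame), non-empty")
  n_ep <- epoch[2] - epoch[1] + 1L
  iv <- intervals
  if (is.null(iv) || nrow(iv) == 0) {
    return(data.frame(epoch = label, active_time = 0, frequency = 0,
                      mean_duration = NA_real_, n_events = 0L,
                      epoch_minutes = n_ep * frame_interval / 60))
  }
  starts_in <- iv[, 1] >= epoch[1] & iv[, 1] <= epoch[2]
  freq <- sum(starts_in) / (n_ep * frame_interval / 60)
  mean_dur <- if (any(starts_in))
    mean((iv[starts_in, 2] - iv[starts_in, 1]) * frame_interval)
  else NA_real_
  # restrict coverage to the epoch for active time
  a <- pmax(iv[, 1], epoch[1]); b <- pmin(iv[, 2], epoch[2] + 1L)
  at <- 100 * sum(pmax(b - a, 0)) / n_ep
  data.frame(epoch = label, active_time = at, frequency = freq,
             mean_duration = mean_dur, n_events = sum(starts_in),
             epoch_minutes = n_ep * frame_interval / 60)
}

#' Classify a ROI as responder
#'
#' A ROI responds when its stimulus-epoch event rate is credibly elevated
#' over baseline: at least one stimulus event, an event frequency at least
#' `1 + min_rel_increase` times the baseline frequency, mean event duration
#' not shrunk below `1 - min_rel_increase` times baseline, and a
#' significant one-sided exact test of the event counts (conditional
#' binomial: given the total count, stimulus events exceed the share
#' expected from the epoch lengths at level `alpha`). This operational
#' rule is a package default; no published criterion exists for it.
#'
#' @param baseline,stimulus single-row data frames from [event_stats()].
#' @param min_rel_increase required relative frequency increase
#'   (default 0.2).
#' @param alpha level of the one-sided count test (default 0.05).
#' @return logical.
#' @export
classify_responder <- function(baseline, stimulus, min_rel_increase = 0.2,
                               alpha = 0.05) {
  if (stimulus$n_events < 1) return(FALSE)
  freq_up <- if (baseline$frequency <= 0) TRUE
  else stimulus$frequency >= baseline$frequency * (1 + min_rel_increase)
  dur_ok <- is.na(baseline$mean_duration) || baseline$mean_duration <= 0 ||
    (!is.na(stimulus$mean_duration) &&
       stimulus$mean_duration >= baseline$mean_duration *
         (1 - min_rel_increase))
  n_tot <- stimulus$n_events + baseline$n_events
  p_stim <- stimulus$epoch_minutes /
    (stimulus$epoch_minutes + baseline$epoch_minutes)
  pval <- stats::binom.test(stimulus$n_events, n_tot, p_stim,
                            alternative = "greater")$p.value
  freq_up && dur_ok && pval < alpha
}

#' Peristimulus average across traces
#'
#' Resamples each trace to a common time axis around its alignment time
#' (onset or offset maps to t = 0) and returns the pointwise mean and SEM
#' (sd / sqrt(n), n - 1 denominator). Traces that do not cover the window
#' are excluded with a warning.
#'
#' @param traces list of `list(time, value)` (or data frames with those
#'   columns).
#' @param align_times numeric vector of alignment times, one per trace.
#' @param window `c(before, after)` seconds around the alignment point.
#' @param dt output sampling step in seconds.
#' @param alignment label, `"onset"` or `"offset"`.
#' @return list of class `peristimulus_average`: `time`, `mean`, `sem`,
#'   `n`, `alignment`.
#' @export
peristimulus_average <- function(traces, align_times, window = c(60, 120),
                                 dt = 1, alignment = "onset") {
  stopifnot(length(traces) == length(align_times))
  tax <- seq(-abs(window[1]), abs(window[2]), by = dt)
  rows <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    t0 <- align_times[i]
    if (min(tr$time) > t0 - abs(window[1]) ||
        max(tr$time) < t0 + abs(window[2])) {
      warning(sprintf("trace %d does not cover the window; excluded", i))
      next
    }
    rows[[length(rows) + 1]] <-
      stats::approx(tr$time - t0, tr$value, xout = tax, rule = 1)$y
  }
  if (length(rows) == 0) abort_field("traces", "no trace covers the window")
  M <- do.call(rbind, rows)
  n <- nrow(M)
  structure(list(time = tax, mean = colMeans(M),
                 sem = if (n > 1) apply(M, 2, stats::sd) / sqrt(n)
                       else rep(0, length(tax)),
                 n = n, alignment = alignment),
            class = "peristimulus_average")
}

#' Per-ROI epoch statistics table
#'
#' Computes baseline / stimulus / post event statistics and the responder
#' call for every ROI. Epochs default to the stimulus window, a pre-onset
#' baseline of equal length, and an equal-length post window after offset
#' (clipped to the recording).
#'
#' @param activity logical matrix `n_frames x n_rois` (e.g. from
#'   [roi_activity()]).
#' @param stim_frames `c(first, last)` stimulus frames (inclusive).
#' @param frame_interval seconds per frame.
#' @param min_duration minimum event length in frames.
#' @param classes optional per-ROI class labels.
#' @param traces optional `n_frames x n_rois` denoised traces; when given,
#'   detected intervals are refined to half-prominence extent with
#'   [refine_intervals()] before statistics are computed.
#' @return data frame with one row per ROI x epoch plus a `responder`
#'   column (repeated across the ROI's rows).
#' @export
roi_event_table <- function(activity, stim_frames, frame_interval = 1,
                            min_duration = 2, classes = NULL,
                            traces = NULL) {
  nt <- nrow(activity); nr <- ncol(activity)
  len <- stim_frames[2] - stim_frames[1] + 1L
  base_ep <- c(max(1L, stim_frames[1] - len), stim_frames[1] - 1L)
  if (base_ep[2] < base_ep[1]) base_ep <- c(1L, stim_frames[1] - 1L)
  post_ep <- c(stim_frames[2] + 1L, min(nt, stim_frames[2] + len))
  out <- list()
  for (i in seq_len(nr)) {
    iv <- intervals_from_mask(activity[, i], frame_interval, min_duration)
    if (!is.null(traces)) iv <- refine_intervals(traces[, i], iv)
    b <- event_stats(iv, base_ep, frame_interval, "baseline")
    s <- event_stats(iv, stim_frames, frame_interval, "stimulus")
    p <- if (post_ep[2] >= post_ep[1])
      event_stats(iv, post_ep, frame_interval, "post") else NULL
    resp <- classify_responder(b, s)
    rows <- rbind(b, s, p)
    rows <- cbind(roi = i,
                  class = if (is.null(classes)) NA_character_ else classes[i],
                  rows, responder = resp)
    out[[i]] <- rows
  }
  do.call(rbind, out)
}
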