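# Synthetic physiological recordings (ICP / ABP / RSNA) with ground truth.
#
# Emulates the raised-ICP stimulus protocol: a minutes-long ICP step of
# 10-15 mmHg delivered from a resting baseline, followed after a delay by a
# pressor response (MAP and heart-rate rise) and a proportional increase in
# the envelope of the raw sympathetic nerve signal, all decaying back to
# baseline over a persistence window after stimulus offset.

#' Parameters of the synthetic physiology generator
#'
#' Defaults plant a 12 mmHg ICP step lasting 5 minutes into a 15-minute
#' recording, a 21 mmHg pressor response and a 49 bpm heart-rate rise
#' starting 32 s after stimulus onset, and a sympathetic envelope gain of
#' 1.9 % of resting activity per mmHg of pressor response.
#'
#' @param duration recording length, seconds.
#' @param sample_rate sampling rate, Hz.
#' @param icp_baseline,icp_step resting ICP and planted step size, mmHg.
#' @param step_onset,step_duration stimulus onset time and duration, seconds.
#' @param step_rise ICP rise/fall ramp time, seconds.
#' @param map_baseline resting mean arterial pressure, mmHg.
#' @param pressor_amplitude planted MAP response, mmHg.
#' @param hr_baseline resting heart rate, bpm.
#' @param hr_delta planted heart-rate response, bpm.
#' @param pulse_amplitude arterial pulse wave amplitude around MAP, mmHg.
#' @param response_delay seconds between stimulus onset and response onset.
#' @param response_rise response rise ramp, seconds.
#' @param response_persistence seconds after stimulus offset until the
#'   response has returned to baseline (linear decay).
#' @param rsna_gain sympathetic envelope gain, percent of resting activity
#'   per mmHg of pressor response.
#' @param rsna_carrier_sd resting RSNA carrier noise SD, volts.
#' @param icp_noise_sd,abp_noise_sd additive measurement noise SD, mmHg.
#' @param seed integer RNG seed.
#' @return a validated `synthetic_physio_params` list.
#' @export
physio_params <- function(duration = 900, sample_rate = 250,
                          icp_baseline = 5, icp_step = 12,
                          step_onset = 300, step_duration = 300,
                          step_rise = 5,
                          map_baseline = 100, pressor_amplitude = 21,
                          hr_baseline = 360, hr_delta = 49,
                          pulse_amplitude = 20,
                          response_delay = 32, response_rise = 10,
                          response_persistence = 120,
                          rsna_gain = 1.9, rsna_carrier_sd = 0.1,
                          icp_noise_sd = 0.3, abp_noise_sd = 1,
                          seed = 1) {
  p <- as.list(environment())
  check_scalar(p$duration, "duration", lower = 1)
  check_scalar(p$sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar(p$icp_step, "icp_step", lower = 0)
  check_scalar(p$step_onset, "step_onset", lower = 0)
  check_scalar(p$step_duration, "step_duration", lower = 0, strict_lower = TRUE)
  if (p$step_onset + p$step_duration > p$duration)
    abort_field("step_duration", "step_onset + step_duration must be <= duration")
  check_scalar(p$response_delay, "response_delay", lower = 0)
  check_scalar(p$response_rise, "response_rise", lower = 0, strict_lower = TRUE)
  check_scalar(p$response_persistence, "response_persistence", lower = 0,
               strict_lower = TRUE)
  check_scalar(p$pressor_amplitude, "pressor_amplitude", lower = 0)
  check_scalar(p$rsna_gain, "rsna_gain", lower = 0)
  for (f in c("rsna_carrier_sd", "icp_noise_sd", "abp_noise_sd"))
    check_scalar(p[[f]], f, lower = 0)
  check_scalar(p$seed, "seed", integerish = TRUE)
  class(p) <- "synthetic_physio_params"
  p
}

#' Physiological recording container
#'
#' Uniformly sampled ICP, arterial pressure waveform and raw sympathetic
#' nerve activity sharing one time axis.
#'
#' @param time seconds (uniform).
#' @param icp intracranial pressure, mmHg.
#' @param abp arterial blood pressure waveform, mmHg.
#' @param rsna_raw raw sympathetic nerve signal, volts.
#' @param sample_rate Hz.
#' @return an object of class `physio_recording`.
#' @export
physio_recording <- function(time, icp, abp, rsna_raw, sample_rate) {
  n <- length(time)
  if (length(icp) != n || length(abp) != n || length(rsna_raw) != n)
    abort_field("icp/abp/rsna_raw", "all channels must share the time axis length")
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  structure(list(time = time, icp = icp, abp = abp, rsna_raw = rsna_raw,
                 sample_rate = sample_rate),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %.1f s at %g Hz (%d samples)\n",
              max(x$time), x$sample_rate, length(x$time)))
  invisible(x)
}

#' @export
as.data.frame.physio_recording <- function(x, ...) {
  data.frame(time = x$time, icp = x$icp, abp = x$abp, rsna = x$rsna_raw)
}

# Piecewise-linear ramp: 0 before on, 1 after on + rise.
ramp_up <- function(t, on, rise) pmin(pmax((t - on) / rise, 0), 1)

# Stimulus shape: linear rise over step_rise, plateau, linear fall.
stimulus_shape <- function(t, onset, offset, rise) {
  ramp_up(t, onset, rise) - ramp_up(t, offset, rise)
}

# Delayed response shape: rises at onset + delay, plateau, linear decay to
# zero at offset + persistence.
response_shape <- function(t, onset, offset, delay, rise, persistence) {
  up <- ramp_up(t, onset + delay, rise)
  down <- ramp_up(t, offset, persistence)
  pmax(up - down, 0)
}

#' Generate a synthetic physiological recording with ground truth
#'
#' @param params a [physio_params()] object.
#' @return list with `recording` (a [physio_recording()]) and `truth`
#'   (stimulus onset/offset, planted response onset and delay, pressor and
#'   heart-rate amplitudes, sympathetic change in percent of resting, and
#'   the planted persistence).
#' @export
generate_physio <- function(params) {
  p <- if (inherits(params, "synthetic_physio_params")) params
       else do.call(physio_params, params)
  with_seed(p$seed, {
    n <- round(p$duration * p$sample_rate)
    t <- (seq_len(n) - 1L) / p$sample_rate
    onset <- p$step_onset; offset <- p$step_onset + p$step_duration

    stim <- stimulus_shape(t, onset, offset, p$step_rise)
    resp <- response_shape(t, onset, offset, p$response_delay,
                           p$response_rise, p$response_persistence)

    icp <- p$icp_baseline + p$icp_step * stim
    if (p$icp_noise_sd > 0) icp <- icp + stats::rnorm(n, 0, p$icp_noise_sd)

    map_t <- p$map_baseline + p$pressor_amplitude * resp
    hr_t <- p$hr_baseline + p$hr_delta * resp
    phase <- 2 * pi * cumsum(hr_t / 60) / p$sample_rate
    abp <- map_t + p$pulse_amplitude * sin(phase)
    if (p$abp_noise_sd > 0) abp <- abp + stats::rnorm(n, 0, p$abp_noise_sd)

    envelope <- 1 + (p$rsna_gain * p$pressor_amplitude / 100) * resp
    rsna <- envelope * stats::rnorm(n, 0, max(p$rsna_carrier_sd, 1e-12))
    if (p$rsna_carrier_sd == 0) rsna <- numeric(n)

    truth <- list(stimulus_onset = onset, stimulus_offset = offset,
                  response_onset = onset + p$response_delay,
                  response_delay = p$response_delay,
                  pressor_amplitude = p$pressor_amplitude,
                  hr_delta = p$hr_delta,
                  rsna_delta_pct = p$rsna_gain * p$pressor_amplitude,
                  persistence = p$response_persistence,
                  map_trace = map_t, hr_trace = hr_t,
                  params = p)
    list(recording = physio_recording(t, icp, abp, rsna, p$sample_rate),
         truth = truth)
  })
}

#' Write / read a physiological recording as CSV with a JSON sidecar
#'
#' CSV columns are `time, icp, abp, rsna`; the sidecar stores the sample
#' rate (and, when written from a synthetic recording, the ground truth).
#'
#' @param rec a [physio_recording()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @param truth optional ground-truth list to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_physio_csv <- function(rec, path, truth = NULL) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  side <- list(sample_rate = rec$sample_rate)
  if (!is.null(truth))
    side$truth <- truth[setdiff(names(truth), c("map_trace", "hr_trace", "params"))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_physio_csv
#' @export
read_physio_csv <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  physio_recording(d$time, d$icp, d$abp, d$rsna, side$sample_rate)
}
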