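## Parametric epicardial electrogram template. The experimental sock
## waveforms are not parameterized anywhere, so this biphasic RS template
## (derivative-of-Gaussian QRS with a smooth downstroke as the intrinsic
## deflection, plus an optional T wave) is this package's own construction;
## see the methods vignette.

#' Beat template
#'
#' @param qrs_duration_ms QRS complex duration (> 0).
#' @param rs_amplitude_mV peak-to-peak amplitude of the rendered QRS.
#' @param t_wave include a T wave?
#' @param t_duration_ms T wave duration.
#' @param t_amplitude_rel T peak amplitude relative to RS peak-to-peak.
#' @param qrs_onset_ms flat isoelectric lead-in before the QRS within each
#'   cycle (leaves room for the pre-QRS noise/isoelectric windows).
#' @param cycle_length_ms pacing cycle length.
#' @return object of class `beat_template`.
#' @export
beat_template <- function(qrs_duration_ms = 80, rs_amplitude_mV = 10,
                          t_wave = TRUE, t_duration_ms = 150,
                          t_amplitude_rel = 0.15,
                          qrs_onset_ms = 100, cycle_length_ms = 700) {
  if (qrs_duration_ms <= 0) stopf("qrs_duration_ms must be > 0")
  if (cycle_length_ms <= qrs_onset_ms + qrs_duration_ms) {
    stopf("cycle length too short for QRS window")
  }
  structure(list(qrs_duration_ms = qrs_duration_ms,
                 rs_amplitude_mV = rs_amplitude_mV,
                 t_wave = t_wave, t_duration_ms = t_duration_ms,
                 t_amplitude_rel = t_amplitude_rel,
                 qrs_onset_ms = qrs_onset_ms,
                 cycle_length_ms = cycle_length_ms),
            class = "beat_template")
}

#' Render a beat template at a sampling rate
#'
#' @param template a `beat_template`.
#' @param fs_hz sampling rate.
#' @return numeric vector of one cycle (mV), with attributes `qrs_on`,
#'   `qrs_off`, `t_off` (1-based samples) and `id_sample`, the intrinsic
#'   deflection (steepest downstroke) sample.
#' @export
render_template <- function(template, fs_hz) {
  n <- ms_to_samples(template$cycle_length_ms, fs_hz)
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  mu <- template$qrs_onset_ms + template$qrs_duration_ms / 2
  sg <- template$qrs_duration_ms / 8
  z <- (t_ms - mu) / sg
  qrs <- -z * exp(-z^2 / 2)          # R upstroke, steep downstroke at mu, S
  qrs <- qrs / diff(range(qrs)) * template$rs_amplitude_mV
  v <- qrs
  t_off_ms <- template$qrs_onset_ms + template$qrs_duration_ms
  if (template$t_wave) {
    tc <- t_off_ms + 0.5 * template$t_duration_ms
    ts <- template$t_duration_ms / 6
    v <- v + template$t_amplitude_rel * template$rs_amplitude_mV *
      exp(-((t_ms - tc) / ts)^2 / 2)
    t_off_ms <- t_off_ms + template$t_duration_ms
  }
  ## flush denormal-scale Gaussian tails to an exactly flat diastole so
  ## repeated beats are bit-identical (no sub-1e-12 leakage across cycles)
  v[abs(v) < 1e-12 * max(abs(v))] <- 0
  qrs_on <- ms_to_samples(template$qrs_onset_ms, fs_hz)
  qrs_off <- ms_to_samples(template$qrs_onset_ms + template$qrs_duration_ms, fs_hz)
  structure(v,
            qrs_on = qrs_on, qrs_off = qrs_off,
            t_off = min(n, ms_to_samples(t_off_ms, fs_hz)),
            id_sample = which.min(diff(v)))
}

#' Simulate paced multi-beat epicardial recordings
#'
#' Every lead shows the template time-shifted by its activation time in each
#' beat; beat onsets are separated by the cycle length plus Gaussian jitter.
#' The recording carries the ground-truth beat segmentation (QRS windows
#' covering all leads' shifted QRS, pre-QRS isoelectric windows, QRST
#' windows).
#'
#' @param act_map an `activation_map` (one time per lead/node).
#' @param template a `beat_template`.
#' @param n_beats number of beats (>= 1).
#' @param fs_hz sampling rate; must be at least 4x the template's maximum
#'   frequency content (checked against the QRS deflection bandwidth).
#' @param jitter_ms SD of beat-onset jitter (ms).
#' @param iso_len_ms length of the recorded isoelectric window (20 ms for the
#'   50 Hz dialect, 17 ms for 60 Hz).
#' @param seed RNG seed for the jitter.
#' @return a `potential_recording` (leads = map nodes).
#' @export
simulate_epicardial_beats <- function(act_map, template, n_beats = 5,
                                      fs_hz = 1000, jitter_ms = 0,
                                      iso_len_ms = 20, seed = NULL) {
  if (n_beats < 1) stopf("n_beats must be >= 1")
  ## deflection time-scale sigma (ms) ~ qrs/8; content extends to roughly
  ## 1/(2*pi*sigma) * 5; require fs >= 4x that
  f_max <- 5000 / (2 * pi * template$qrs_duration_ms / 8)
  if (fs_hz < 4 * f_max) {
    stopf("fs_hz (%g) below 4x template frequency content (%.0f Hz)", fs_hz, f_max)
  }
  tmpl <- render_template(template, fs_hz)
  len <- length(tmpl)
  shifts <- as.integer(round(act_map$times_ms * fs_hz / 1000))
  if (min(shifts) != 0L) shifts <- shifts - min(shifts)
  if (attr(tmpl, "t_off") + max(shifts) > len) {
    stopf("QRS/T window shifted by activation exceeds cycle length")
  }
  jit <- with_seed(seed, c(0, round(rnorm(n_beats - 1, 0, jitter_ms * fs_hz / 1000))))
  onsets <- as.integer((seq_len(n_beats) - 1L) * len + cumsum(jit))
  if (is.unsorted(onsets, strictly = TRUE)) stopf("jitter exceeds cycle length")
  n_leads <- length(shifts)
  total <- onsets[n_beats] + len + max(shifts)
  values <- matrix(0, n_leads, total)
  for (b in seq_len(n_beats)) {
    for (i in seq_len(n_leads)) {
      idx <- onsets[b] + shifts[i] + seq_len(len)
      values[i, idx] <- values[i, idx] + tmpl
    }
  }
  qrs_on <- onsets + min(shifts) + attr(tmpl, "qrs_on")
  qrs_off <- onsets + max(shifts) + attr(tmpl, "qrs_off")
  qrst_off <- onsets + max(shifts) + attr(tmpl, "t_off")
  iso_len <- ms_to_samples(iso_len_ms, fs_hz)
  seg <- beat_segmentation(onset = onsets + 1L,
                           qrs_on = qrs_on, qrs_off = qrs_off,
                           iso_on = qrs_on - iso_len, iso_len = iso_len,
                           qrst_on = qrs_on, qrst_off = qrst_off)
  rec <- potential_recording(values, fs_hz, segmentation = seg)
  attr(rec, "template_id_sample") <- attr(tmpl, "id_sample")
  attr(rec, "shifts") <- shifts
  rec
}
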