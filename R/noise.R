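## Measurement-noise model for torso recordings: power-line interference
## (per-lead random phase, with harmonics), broadband Gaussian channel noise,
## and low-frequency baseline wander.

#' Noise specification
#'
#' @param line_freq_hz power-line frequency, 50 or 60 Hz.
#' @param line_amp_mV per-lead line-sinusoid amplitude (>= 0).
#' @param white_sd_mV Gaussian channel-noise SD (>= 0).
#' @param drift_amp_mV baseline-wander amplitude (>= 0).
#' @param drift_freq_hz length-2 frequency band of the wander; must lie at or
#'   below 0.5 Hz.
#' @param harmonics number of line-frequency harmonics added above the
#'   fundamental (amplitude of harmonic h scaled by 1/(h+1)).
#' @param seed RNG seed; identical seed gives bit-identical noise.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(line_freq_hz = 50, line_amp_mV = 0.2,
                       white_sd_mV = 0.05, drift_amp_mV = 1.0,
                       drift_freq_hz = c(0.05, 0.25), harmonics = 2,
                       seed = 1) {
  if (!line_freq_hz %in% c(50, 60)) stopf("line_freq_hz must be 50 or 60")
  if (line_amp_mV < 0 || white_sd_mV < 0 || drift_amp_mV < 0) {
    stopf("noise amplitudes must be >= 0")
  }
  if (length(drift_freq_hz) == 1) drift_freq_hz <- rep(drift_freq_hz, 2)
  if (max(drift_freq_hz) > 0.5 || max(drift_freq_hz) >= 0.5 * line_freq_hz) {
    stopf("drift band must lie at or below 0.5 Hz")
  }
  structure(list(line_freq_hz = line_freq_hz, line_amp_mV = line_amp_mV,
                 white_sd_mV = white_sd_mV, drift_amp_mV = drift_amp_mV,
                 drift_freq_hz = sort(drift_freq_hz), harmonics = harmonics,
                 seed = seed),
            class = "noise_spec")
}

## Realize the three noise components for n_leads x n_samples at fs_hz.
## Returns list(line, white, drift) matrices; pure function of (spec, dims).
realize_noise <- function(spec, n_leads, n_samples, fs_hz) {
  t_s <- (seq_len(n_samples) - 1) / fs_hz
  with_seed(spec$seed, {
    line <- matrix(0, n_leads, n_samples)
    if (spec$line_amp_mV > 0) {
      for (h in 0:spec$harmonics) {
        f <- spec$line_freq_hz * (h + 1)
        if (f >= fs_hz / 2) break
        phase <- runif(n_leads, 0, 2 * pi)
        amp <- spec$line_amp_mV / (h + 1)
        line <- line + amp * sin(outer(rep(2 * pi * f, n_leads), t_s) +
                                   matrix(phase, n_leads, n_samples))
      }
    }
    white <- matrix(rnorm(n_leads * n_samples, 0, spec$white_sd_mV),
                    n_leads, n_samples)
    drift <- matrix(0, n_leads, n_samples)
    if (spec$drift_amp_mV > 0) {
      ## sum of 3 random-phase sinusoids per lead, frequencies in the band,
      ## amplitudes tapering 1, 1/2, 1/3
      for (k in 1:3) {
        f <- runif(n_leads, spec$drift_freq_hz[1], spec$drift_freq_hz[2])
        phase <- runif(n_leads, 0, 2 * pi)
        drift <- drift + (spec$drift_amp_mV / k) *
          sin(outer(2 * pi * f, t_s) + matrix(phase, n_leads, n_samples))
      }
    }
    list(line = line, white = white, drift = drift)
  })
}

#' Project epicardial potentials to the torso and add noise
#'
#' Forms y(t) = A x(t) + n(t): the forward transfer of the epicardial
#' recording plus the line, channel and drift noise realized from the spec.
#' With all noise amplitudes zero the output equals A x exactly. The beat
#' segmentation is copied from the epicardial recording.
#'
#' @param forward a `forward_model` whose source dimension matches the
#'   epicardial lead count.
#' @param epi a `potential_recording` of epicardial potentials.
#' @param noise a `noise_spec`.
#' @return a `potential_recording` of torso potentials.
#' @export
generate_torso_recording <- function(forward, epi, noise = noise_spec()) {
  A <- forward$A
  if (ncol(A) != nrow(epi$values)) {
    stopf("forward source dimension (%d) does not match epicardial lead count (%d)",
          ncol(A), nrow(epi$values))
  }
  y <- A %*% epi$values
  nz <- realize_noise(noise, nrow(y), ncol(y), epi$fs_hz)
  potential_recording(y + nz$line + nz$white + nz$drift, epi$fs_hz,
                      segmentation = epi$segmentation)
}
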