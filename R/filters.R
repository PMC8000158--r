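## The 49-variant torso-signal processing bank: seven high-frequency removal
## (HFR) methods, five baseline-drift removal (BDR) methods, their 35
## compositions, the raw signal, and PCA-based signal averaging.
##
## Window lengths follow the two acquisition dialects: one line cycle is
## 20 ms at 50 Hz and 17 ms at 60 Hz; the Pipberger window is two cycles
## (40/33 ms). Every stage is zero-phase -- phase shifts would bias
## activation-time placement. Edge handling: moving averages reflect the
## record symmetrically, Savitzky-Golay uses its least-squares edge
## windows, the Butterworth stages act on the mirror-extended record.

hfr_ids <- function() paste0("HFR", 1:7)
bdr_ids <- function() paste0("BDR", 1:5)

## symmetric (repeating) reflection padding of matrix rows
pad_reflect <- function(X, p) {
  n <- ncol(X)
  p <- min(p, n)
  cbind(X[, p:1, drop = FALSE], X, X[, n:(n - p + 1), drop = FALSE])
}

## centered FIR filtering of every row with an odd-length kernel,
## reflection-padded
fir_rows <- function(X, w) {
  stopifnot(length(w) %% 2L == 1L)
  h <- (length(w) - 1L) %/% 2L
  n <- ncol(X)
  if (length(w) > n + 2 * min(h, n)) stopf("filter frame longer than record")
  Xp <- pad_reflect(X, h)
  out <- matrix(0, nrow(X), n)
  for (m in seq_along(w)) {
    out <- out + w[m] * Xp[, (m - 1L) + seq_len(n), drop = FALSE]
  }
  out
}

## full-cycle averaging window: spans round(fs/f0) sample intervals with
## half-weight endpoints (trapezoid), annihilating the line frequency and
## its harmonics exactly when fs/f0 is an integer; falls back to a plain
## odd boxcar when the span is odd (non-integer cycle anyway)
line_cycle_window <- function(fs_hz, line_freq_hz) {
  n_int <- round(fs_hz / line_freq_hz)
  if (n_int %% 2L == 0L) {
    w <- c(0.5, rep(1, n_int - 1L), 0.5)
  } else {
    w <- rep(1, n_int)
  }
  w / sum(w)
}

## two-cycle raised-cosine (Pipberger) window; exact line-frequency zero
## when two cycles fit an even sample span
pipberger_window <- function(fs_hz, line_freq_hz) {
  n_int <- round(2 * fs_hz / line_freq_hz)
  if (n_int %% 2L == 1L) n_int <- n_int - 1L
  k <- 0:n_int
  w <- 0.5 * (1 - cos(2 * pi * k / n_int))
  w / sum(w)
}

notch_rows <- function(X, fs_hz, line_freq_hz, half_width_hz = 1) {
  n <- ncol(X)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)              # two-sided bin frequencies
  harm <- seq(line_freq_hz, fs_hz / 2, by = line_freq_hz)
  kill <- rep(FALSE, n)
  for (h in harm) kill <- kill | abs(f - h) <= half_width_hz
  Xf <- t(mvfft(t(X)))
  Xf[, kill] <- 0
  Re(t(mvfft(t(Xf), inverse = TRUE))) / n
}

## Savitzky-Golay smoothing of every row. No reflection padding here: the
## startup/ending rows of the projection matrix fit the polynomial to the
## partial edge windows, which reproduces polynomial trends exactly at the
## record ends (reflection would not). The projection matrix is built once
## and applied to all leads (sgolayfilt would rebuild it per lead, which at
## the 3000 ms baseline frame dominates the run time).
sgolay_rows <- function(X, order, frame) {
  if (frame %% 2L == 0L) frame <- frame + 1L
  n <- ncol(X)
  if (frame > n) stopf("Savitzky-Golay frame (%d) longer than record (%d)", frame, n)
  Fm <- signal::sgolay(p = order, n = frame)
  k <- (frame - 1L) %/% 2L
  mid <- Fm[k + 1L, ]                      # symmetric centered FIR
  out <- t(stats::filter(t(X), rev(mid), method = "convolution", sides = 2))
  out[, seq_len(k)] <- X[, seq_len(frame), drop = FALSE] %*%
    t(Fm[seq_len(k), , drop = FALSE])
  out[, n - k + seq_len(k)] <- X[, n - frame + seq_len(frame), drop = FALSE] %*%
    t(Fm[k + 1L + seq_len(k), , drop = FALSE])
  out
}

## Zero-phase (forward-backward) Butterworth on each row, realized
## spectrally: the squared digital Butterworth magnitude (bilinear design
## with tan prewarping, the response a forward-backward recursion applies)
## is imposed on the mirror-extended record. This sidesteps the severe
## round-off a direct transfer-function recursion suffers at deep
## normalized cutoffs (0.5 Hz at 1000 Hz), is exactly linear and exactly
## zero-phase, and gives unit (low-pass) / zero (high-pass) DC gain to
## machine precision.
butter_rows <- function(X, order, cutoff_hz, fs_hz, type) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    stopf("cutoff must lie inside (0, fs/2)")
  }
  n <- ncol(X)
  Xe <- cbind(X, X[, n:1, drop = FALSE])         # whole-record mirror
  m <- 2L * n
  f <- (seq_len(m) - 1) * fs_hz / m
  f <- pmin(f, fs_hz - f)
  ratio <- tan(pi * f / fs_hz) / tan(pi * cutoff_hz / fs_hz)
  G <- if (type == "high") {
    ifelse(f == 0, 0, 1 / (1 + (1 / ratio)^(2 * order)))
  } else {
    ifelse(f == fs_hz / 2, 0, 1 / (1 + ratio^(2 * order)))
  }
  Xf <- t(mvfft(t(Xe))) * rep(G, each = nrow(X))
  out <- Re(t(mvfft(t(Xf), inverse = TRUE))) / m
  out[, seq_len(n), drop = FALSE]
}

#' Apply a high-frequency removal method
#'
#' * HFR1: moving average over one line cycle.
#' * HFR2: Pipberger cosine-weighted average over two line cycles.
#' * HFR3: Fourier notch at the line frequency and its harmonics.
#' * HFR4: Savitzky-Golay, order 3, frame one line cycle.
#' * HFR5: 11-tap weighted (triangular) running average.
#' * HFR6/HFR7: order-7 Butterworth low-pass at 30/60 Hz, zero phase.
#'
#' @param rec a `potential_recording`.
#' @param method one of "HFR1".."HFR7".
#' @param line_freq_hz acquisition dialect, 50 or 60 Hz.
#' @param notch_half_width_hz half-width of the HFR3 notch (Hz).
#' @param hfr5_kernel optional replacement kernel for HFR5 (odd length,
#'   normalized internally).
#' @return filtered `potential_recording` of identical layout.
#' @export
apply_hfr <- function(rec, method, line_freq_hz = 50,
                      notch_half_width_hz = 1, hfr5_kernel = NULL) {
  X <- rec$values
  fs <- rec$fs_hz
  Y <- switch(as.character(method),
    HFR1 = fir_rows(X, line_cycle_window(fs, line_freq_hz)),
    HFR2 = fir_rows(X, pipberger_window(fs, line_freq_hz)),
    HFR3 = notch_rows(X, fs, line_freq_hz, notch_half_width_hz),
    HFR4 = sgolay_rows(X, 3, ms_to_odd_samples(1000 / line_freq_hz, fs)),
    HFR5 = {
      w <- hfr5_kernel %||% c(1:6, 5:1)
      fir_rows(X, w / sum(w))
    },
    HFR6 = butter_rows(X, 7, 30, fs, "low"),
    HFR7 = butter_rows(X, 7, 60, fs, "low"),
    stopf("unknown HFR method: %s", method))
  replace_values(rec, Y)
}

#' Apply a baseline-drift removal method
#'
#' * BDR1: subtract each beat's pre-QRS isoelectric-window mean, per lead.
#' * BDR2: wavelet bandpass 0.5-150 Hz (Coiflet, 4 vanishing moments,
#'   20 decomposition levels requested).
#' * BDR3: subtract an order-3 Savitzky-Golay smooth with a 3000 ms frame
#'   (the smooth is the baseline estimate).
#' * BDR4: subtract a cubic interpolant through the isoelectric-point values.
#' * BDR5: order-5 Butterworth high-pass at 0.5 Hz, zero phase.
#'
#' @param rec a `potential_recording`; BDR1/BDR4 require its segmentation.
#' @param method one of "BDR1".."BDR5".
#' @return filtered `potential_recording`.
#' @export
apply_bdr <- function(rec, method) {
  X <- rec$values
  fs <- rec$fs_hz
  seg <- rec$segmentation
  Y <- switch(as.character(method),
    BDR1 = {
      need_segmentation(seg, "BDR1")
      bdr1_rows(X, seg)
    },
    BDR2 = wavelet_bandpass(X, fs),
    BDR3 = X - sgolay_rows(X, 3, ms_to_odd_samples(3000, fs)),
    BDR4 = {
      need_segmentation(seg, "BDR4")
      X - bdr4_baseline(X, seg)
    },
    BDR5 = butter_rows(X, 5, 0.5, fs, "high"),
    stopf("unknown BDR method: %s", method))
  replace_values(rec, Y)
}

need_segmentation <- function(seg, method) {
  if (is.null(seg) || nrow(seg) == 0) {
    stopf("%s requires beat segmentation with isoelectric windows", method)
  }
}

## piecewise-constant isoelectric correction: each sample belongs to the
## beat whose onset precedes it (samples before beat 1 use beat 1)
bdr1_rows <- function(X, seg) {
  n <- ncol(X)
  iso_means <- sapply(seg$beat, function(b) {
    rowMeans(X[, seg_window(seg, b, "iso"), drop = FALSE])
  })                                    # leads x beats
  iso_means <- matrix(iso_means, nrow = nrow(X))
  beat_of <- findInterval(seq_len(n), seg$onset)
  beat_of[beat_of == 0L] <- 1L
  X - iso_means[, beat_of, drop = FALSE]
}

## cubic interpolant (FMM end conditions: reproduces global cubics exactly)
## through the isoelectric points, per lead. The anchor is the sample at
## each beat's isoelectric-window center (value and abscissa at the same
## sample, so a polynomial baseline is interpolated without window-average
## bias).
bdr4_baseline <- function(X, seg) {
  centers <- round(seg$iso_on + (seg$iso_len - 1) / 2)
  vals <- X[, centers, drop = FALSE]
  xs <- seq_len(ncol(X))
  t(apply(vals, 1, function(v) {
    if (length(centers) >= 4) {
      splinefun(centers, v, method = "fmm")(xs)
    } else if (length(centers) >= 2) {
      approx(centers, v, xout = xs, rule = 2)$y
    } else {
      rep(v, length(xs))
    }
  }))
}

replace_values <- function(rec, Y) {
  dimnames(Y) <- NULL
  rec$values <- Y
  rec
}

#' Apply an HFR method followed by a BDR method
#'
#' Bit-identical to composing [apply_hfr()] and [apply_bdr()]: the HFR runs
#' on the raw signal first, then the BDR on its output.
#'
#' @inheritParams apply_hfr
#' @param hfr,bdr method identifiers.
#' @return filtered `potential_recording`.
#' @export
apply_combined <- function(rec, hfr, bdr, line_freq_hz = 50, ...) {
  apply_bdr(apply_hfr(rec, hfr, line_freq_hz = line_freq_hz, ...), bdr)
}

#' Filter-bank specification
#'
#' @param id method identifier: "RAW", "HFR1".."HFR7", "BDR1".."BDR5",
#'   "HFRi+BDRj", or "SA".
#' @param line_freq_hz dialect (50 or 60 Hz).
#' @return object of class `filter_spec` with fields `id`, `category`
#'   (RAW/HFR/BDR/HFR+BDR/SA), `hfr`, `bdr`, `line_freq_hz`, `lti`.
#' @export
filter_spec <- function(id, line_freq_hz = 50) {
  id <- as.character(id)
  hfr <- bdr <- NA_character_
  if (id == "RAW") {
    category <- "RAW"; lti <- TRUE
  } else if (id == "SA") {
    category <- "SA"; lti <- FALSE
  } else if (grepl("^HFR[1-7]\\+BDR[1-5]$", id)) {
    category <- "HFR+BDR"
    parts <- strsplit(id, "+", fixed = TRUE)[[1]]
    hfr <- parts[1]; bdr <- parts[2]
    lti <- !bdr %in% c("BDR1", "BDR4")
  } else if (id %in% hfr_ids()) {
    category <- "HFR"; hfr <- id; lti <- TRUE
  } else if (id %in% bdr_ids()) {
    category <- "BDR"; bdr <- id; lti <- !id %in% c("BDR1", "BDR4")
  } else {
    stopf("unknown method id: %s", id)
  }
  structure(list(id = id, category = category, hfr = hfr, bdr = bdr,
                 line_freq_hz = line_freq_hz, lti = lti),
            class = "filter_spec")
}

#' Enumerate the full processing bank
#'
#' RAW, the 7 HFR methods, the 5 BDR methods, the 35 HFR+BDR combinations
#' and SA, in stable canonical order: 49 variants.
#'
#' @param line_freq_hz dialect passed to every spec.
#' @return list of `filter_spec`.
#' @export
enumerate_methods <- function(line_freq_hz = 50) {
  ids <- c("RAW", hfr_ids(), bdr_ids(),
           as.vector(t(outer(hfr_ids(), bdr_ids(), paste, sep = "+"))),
           "SA")
  lapply(ids, filter_spec, line_freq_hz = line_freq_hz)
}

#' Apply any filter-bank method by specification
#'
#' @param rec a `potential_recording`.
#' @param spec a `filter_spec` or a method id string.
#' @param ... passed to [apply_hfr()] / [signal_average()].
#' @return filtered `potential_recording` (a single averaged beat for "SA").
#' @export
apply_method <- function(rec, spec, ...) {
  if (is.character(spec)) spec <- filter_spec(spec)
  switch(spec$category,
         RAW = rec,
         HFR = apply_hfr(rec, spec$hfr, line_freq_hz = spec$line_freq_hz, ...),
         BDR = apply_bdr(rec, spec$bdr),
         `HFR+BDR` = apply_combined(rec, spec$hfr, spec$bdr,
                                    line_freq_hz = spec$line_freq_hz, ...),
         SA = signal_average(rec, ...))
}

#' Matrix representation of a linear time-invariant method
#'
#' Returns the n x n operator matrix M with `M %*% s` equal to the filter
#' applied to the single-lead signal `s`. Available for every HFR method and
#' for BDR2/BDR3/BDR5 (and their combinations); BDR1, BDR4 and SA depend on
#' the beat segmentation and have no operator form. Because a purely spatial
#' (static) reconstruction treats every time step independently, any such M
#' commutes with reconstruction at fixed lambda.
#'
#' @param spec a `filter_spec` or method id.
#' @param n_samples signal length.
#' @param fs_hz sampling rate.
#' @return n x n matrix.
#' @export
as_operator <- function(spec, n_samples, fs_hz) {
  if (is.character(spec)) spec <- filter_spec(spec)
  if (!spec$lti || spec$category == "SA") {
    stopf("method %s is segmentation-dependent and has no linear operator form",
          spec$id)
  }
  probe <- potential_recording(diag(n_samples), fs_hz)
  t(apply_method(probe, spec)$values)
}
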