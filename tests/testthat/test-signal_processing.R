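## Interior-region helper: annihilation/attenuation are steady-state filter
## properties; the symmetric reflection padding used at the record edges
## leaves transients inside half a frame of each end, so they are asserted
## away from the edges.
interior <- function(n, margin) (margin + 1):(n - margin)

test_that("the method census enumerates 49 uniquely identified variants", {
  specs <- enumerate_methods()
  ids <- vapply(specs, `[[`, character(1), "id")
  expect_length(specs, 49)
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(sum(vapply(specs, `[[`, character(1), "category") == "HFR+BDR"), 35)
  expect_equal(sum(ids == "RAW"), 1)
  expect_equal(sum(ids == "SA"), 1)
  expect_error(filter_spec("HFR9"), "unknown")
})

test_that("full-cycle averagers annihilate the line frequency", {
  fs <- 1000
  t_s <- (0:999) / fs
  s <- matrix(sin(2 * pi * 50 * t_s + 0.3), 1)
  rec <- potential_recording(s, fs)
  for (m in c("HFR1", "HFR2")) {
    out <- apply_hfr(rec, m, 50)$values
    expect_lt(max(abs(out[1, interior(1000, 50)])) / max(abs(s)), 1e-10)
  }
  ## HFR1 also kills harmonics (trapezoid full-cycle window)
  s2 <- matrix(sin(2 * pi * 150 * t_s + 1), 1)
  out2 <- apply_hfr(potential_recording(s2, fs), "HFR1", 50)$values
  expect_lt(max(abs(out2[1, interior(1000, 50)])), 1e-10)
})

test_that("the Fourier notch removes the line and harmonics but nothing else", {
  fs <- 1000
  t_s <- (0:1999) / fs
  s <- matrix(sin(2 * pi * 10 * t_s) + sin(2 * pi * 50 * t_s), 1)
  out <- apply_hfr(potential_recording(s, fs), "HFR3", 50)$values[1, ]
  sp <- fft(out)
  n <- length(out)          # 2000 samples: 10 and 50 Hz land on exact bins
  amp_at <- function(f_hz) 2 * Mod(sp[round(f_hz * n / fs) + 1]) / n
  expect_lt(abs(amp_at(10) - 1), 0.01)
  expect_lt(amp_at(50), 1e-6)
  ## broadband power outside the notch bands is untouched
  set.seed(7)
  w <- matrix(rnorm(n), 1)
  wf <- apply_hfr(potential_recording(w, fs), "HFR3", 50)$values[1, ]
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  outside <- !sapply(f, function(ff) any(abs(ff - seq(50, 500, 50)) <= 1.5))
  p_in <- sum(Mod(fft(w[1, ]))[outside]^2)
  p_out <- sum(Mod(fft(wf))[outside]^2)
  expect_lt(abs(p_out - p_in) / p_in, 0.01)
})

test_that("Butterworth stages match their analytic zero-phase magnitude response", {
  fs <- 1000; n <- 10000
  imp <- matrix(0, 1, n); imp[1, n / 2] <- 1
  rec <- potential_recording(imp, fs)
  f <- (0:(n - 1)) * fs / n
  sel <- which(f >= 0.1 & f <= 200)
  cases <- list(list(id = "HFR6", ord = 7, fc = 30, hp = FALSE),
                list(id = "HFR7", ord = 7, fc = 60, hp = FALSE),
                list(id = "BDR5", ord = 5, fc = 0.5, hp = TRUE))
  for (cs in cases) {
    out <- if (cs$hp) apply_bdr(rec, cs$id) else apply_hfr(rec, cs$id, 50)
    H <- abs(fft(out$values[1, ]))
    ratio <- tan(pi * f[sel] / fs) / tan(pi * cs$fc / fs)
    Ha <- if (cs$hp) 1 / (1 + (1 / ratio)^(2 * cs$ord)) else
      1 / (1 + ratio^(2 * cs$ord))   # squared magnitude: forward-backward
    expect_lt(max(abs(H[sel] - Ha)), 0.01)
  }
})

test_that("low-pass filtering attenuates out-of-band white noise by >= 40 dB", {
  fs <- 1000; n <- 8192
  set.seed(3)
  w <- matrix(rnorm(n), 1)
  out <- apply_hfr(potential_recording(w, fs), "HFR6", 50)$values[1, ]
  f <- (0:(n - 1)) * fs / n
  band <- f > 60 & f < 500
  p_in <- mean(Mod(fft(w[1, ]))[band]^2)
  p_out <- mean(Mod(fft(out))[band]^2)
  expect_gt(10 * log10(p_in / p_out), 40)
})

test_that("every HFR method has unit DC gain and every BDR method zero DC gain", {
  rec <- make_test_recording(n_leads = 2)
  cst <- potential_recording(matrix(2.5, 2, ncol(rec$values)), rec$fs_hz,
                             segmentation = rec$segmentation)
  for (m in paste0("HFR", 1:7)) {
    expect_lt(max(abs(apply_hfr(cst, m, 50)$values - 2.5)), 1e-9)
  }
  for (m in paste0("BDR", 1:5)) {
    expect_lt(max(abs(apply_bdr(cst, m)$values)), 1e-9)
  }
})

test_that("all methods except SA are linear", {
  rec <- make_test_recording(n_leads = 2, white = 0.1, drift = 0.5, line = 0.3)
  set.seed(4)
  X1 <- rec$values
  X2 <- matrix(rnorm(length(X1), 0, 0.5), nrow(X1))
  mk <- function(X) potential_recording(X, rec$fs_hz, segmentation = rec$segmentation)
  ids <- c(paste0("HFR", 1:7), paste0("BDR", 1:5), "HFR3+BDR2", "HFR6+BDR1")
  for (id in ids) {
    lhs <- apply_method(mk(2 * X1 - 3 * X2), id)$values
    rhs <- 2 * apply_method(mk(X1), id)$values - 3 * apply_method(mk(X2), id)$values
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
  }
})

test_that("zero-phase contract: a symmetric pulse is not displaced", {
  fs <- 1000
  p <- matrix(exp(-((1:1200) - 600)^2 / 50), 1)
  rec <- potential_recording(p, fs)
  for (m in c("HFR1", "HFR2", "HFR4", "HFR5", "HFR6", "HFR7")) {
    out <- apply_hfr(rec, m, 50)$values[1, ]
    expect_equal(which.max(out), 600)
  }
})

test_that("isoelectric correction zeroes the isoelectric mean exactly", {
  rec <- make_test_recording(drift = 1, white = 0.05)
  out <- apply_bdr(rec, "BDR1")
  seg <- out$segmentation
  for (b in seg$beat) {
    iso <- seg$iso_on[b]:(seg$iso_on[b] + seg$iso_len[b] - 1)
    expect_lt(max(abs(rowMeans(out$values[, iso]))), 1e-12)
  }
  expect_error(apply_bdr(potential_recording(rec$values, rec$fs_hz), "BDR1"),
               "segmentation")
})

test_that("wavelet baseline removal takes out sub-0.5 Hz drift and keeps 20 Hz", {
  fs <- 1000; n <- 4096
  t_s <- (0:(n - 1)) / fs
  drift <- 2 * sin(2 * pi * 0.15 * t_s + 0.3)
  sig <- sin(2 * pi * 20 * t_s)
  out <- apply_bdr(potential_recording(matrix(drift + sig, 1), fs), "BDR2")$values[1, ]
  idx <- interior(n, 200)
  expect_lt(sqrt(mean((out[idx] - sig[idx])^2)), 0.05)
})

test_that("long-frame polynomial smoothing removes slow drift from a QRS train", {
  ## T-wave-free beats: the cycle integral is ~0, so the long smooth tracks
  ## the drift rather than residual beat energy
  rec <- make_test_recording(n_leads = 2, tmpl = beat_template(t_wave = FALSE))
  n <- ncol(rec$values)
  u <- (seq_len(n) - 1) / (n - 1)
  drift <- 5 * u^3 - 6 * u + 1.5                                 # slow cubic
  noisy <- potential_recording(sweep(rec$values, 2, -drift), rec$fs_hz,
                               segmentation = rec$segmentation)
  out <- apply_bdr(noisy, "BDR3")
  iso_means <- function(r) sapply(r$segmentation$beat, function(b) {
    mean(r$values[1, r$segmentation$iso_on[b]:(r$segmentation$iso_on[b] + r$segmentation$iso_len[b] - 1)])
  })
  expect_gt(sd(iso_means(noisy)) / sd(iso_means(out)), 10)
  ## record shorter than the 3000 ms frame is rejected
  short <- potential_recording(rec$values[, 1:2000], rec$fs_hz)
  expect_error(apply_bdr(short, "BDR3"), "frame")
})

test_that("cubic-spline baseline removal is exact on a cubic drift", {
  ## compact-support beats (exactly zero through the isoelectric windows),
  ## so the anchors sample the drift alone
  rec <- make_square_beat_recording(n_leads = 2)
  n <- ncol(rec$values)
  x <- seq_len(n) / n
  drift <- 4 * x^3 - 3 * x^2 + 2 * x - 1
  noisy <- potential_recording(sweep(rec$values, 2, -drift), rec$fs_hz,
                               segmentation = rec$segmentation)
  out <- apply_bdr(noisy, "BDR4")
  expect_lt(max(abs(out$values - rec$values)), 1e-6)
})

test_that("combined filtering equals the composition of its parts", {
  rec <- make_test_recording(line = 0.3, white = 0.05, drift = 1)
  expect_identical(apply_combined(rec, "HFR1", "BDR1", 50)$values,
                   apply_bdr(apply_hfr(rec, "HFR1", 50), "BDR1")$values)
  ## all 35 pairs are enumerable and produce distinct outputs
  outs <- list()
  for (h in paste0("HFR", 1:7)) for (b in paste0("BDR", 1:5)) {
    outs[[paste(h, b)]] <- apply_combined(rec, h, b, 50)$values
  }
  expect_length(outs, 35)
  for (i in seq_along(outs)) for (j in seq_len(i - 1)) {
    expect_gt(max(abs(outs[[i]] - outs[[j]])), 0)
  }
})

test_that("notch plus wavelet suppresses both line and drift energy", {
  rec <- make_test_recording(n_leads = 1, line = 0.5, drift = 2)
  out <- apply_combined(rec, "HFR3", "BDR2", 50)
  n <- ncol(rec$values)
  f <- (seq_len(n) - 1) * rec$fs_hz / n
  p_before <- Mod(fft(rec$values[1, ]))^2
  p_after <- Mod(fft(out$values[1, ]))^2
  line_band <- abs(f - 50) <= 1
  drift_band <- f <= 0.5 & f > 0
  expect_lt(sum(p_after[line_band]) / sum(p_before[line_band]), 1e-3)
  expect_lt(sum(p_after[drift_band]) / sum(p_before[drift_band]), 1e-2)
})

test_that("operator matrices reproduce the filters they stand for", {
  fs <- 1000; n <- 400
  set.seed(9)
  X <- matrix(rnorm(3 * n), 3)
  rec <- potential_recording(X, fs)
  for (id in c(paste0("HFR", 1:7), "BDR2", "BDR5", "HFR3+BDR5")) {
    M <- as_operator(id, n, fs)
    direct <- apply_method(rec, id)$values
    via_op <- X %*% t(M)
    expect_lt(max(abs(direct - via_op)) / max(abs(direct)), 1e-8)
  }
  ## moving-average rows are unit-sum boxcars away from the edges
  M1 <- as_operator("HFR1", n, fs)
  expect_equal(unname(rowSums(M1)), rep(1, n), tolerance = 1e-12)
  mid <- M1[200, ]
  expect_equal(sum(mid != 0), 21)
  expect_equal(which(mid != 0), 190:210)
  ## impulse response recovery
  imp <- rep(0, n); imp[200] <- 1
  expect_equal(as.vector(M1 %*% imp), M1[, 200])
  ## segmentation-dependent methods have no operator form
  expect_error(as_operator("BDR1", n, fs), "operator")
  expect_error(as_operator("BDR4", n, fs), "operator")
  expect_error(as_operator("SA", n, fs), "operator")
})

test_that("signal averaging of identical beats reproduces a single beat", {
  rec <- make_test_recording(n_beats = 5, tmpl = beat_template(t_wave = FALSE))
  seg <- rec$segmentation
  ## averaging machinery alone: identical items -> their mean, exactly
  avg0 <- signal_average(rec, baseline_method = "none")
  ref0 <- rec$values[, seg$onset[1]:seg$qrst_off[1]]
  expect_equal(dim(avg0$values), dim(ref0))
  expect_lt(max(abs(avg0$values - ref0)), 1e-9)
  expect_equal(attr(avg0, "n_averaged"), 5)
  ## with the default wavelet stage the beats differ only by the filter's
  ## finite-record leakage (fraction of a percent of the 10 mV amplitude)
  avg <- signal_average(rec)
  ref <- apply_bdr(rec, "BDR2")$values[, seg$onset[1]:seg$qrst_off[1]]
  expect_lt(max(abs(avg$values - ref)), 0.01)
})

test_that("beat alignment recovers a constructed 10-sample shift exactly", {
  rec <- make_test_recording(n_beats = 4)
  seg <- rec$segmentation
  vals <- rec$values
  ## displace beat 3 by +10 samples
  b3 <- seg$onset[3]:(seg$onset[4] - 1)
  seg3 <- vals[, b3]
  vals[, b3] <- 0
  vals[, b3 + 10] <- vals[, b3 + 10] + seg3
  shifted <- potential_recording(vals, rec$fs_hz, segmentation = seg)
  avg <- signal_average(shifted)
  expect_equal(attr(avg, "shifts")[3], 10)
  expect_equal(attr(avg, "shifts")[c(1, 2, 4)], c(0, 0, 0))
})

test_that("averaging n noisy beats shrinks noise like 1/sqrt(n)", {
  ## the averager's internal wavelet stage filters part of the broadband
  ## noise, and its decimated transform retains slightly different noise
  ## power per beat window; the 1/sqrt(n) law therefore applies to the
  ## mean per-beat noise power reaching the averaging stage
  clean <- make_test_recording(n_leads = 6, n_beats = 8)
  noisy <- make_test_recording(n_leads = 6, n_beats = 8, white = 0.2, seed = 12)
  seg <- clean$segmentation
  avg <- signal_average(noisy)
  clean_f <- apply_bdr(clean, "BDR2")
  noisy_f <- apply_bdr(noisy, "BDR2")
  wlen <- seg$qrst_off[1] - seg$onset[1] + 1L
  wins <- lapply(seg$beat, function(b) seg$onset[b] + seq_len(wlen) - 1L)
  ## the signal part of the average is the mean clean filtered window
  ## (alignment shifts are zero here), so subtracting it isolates the noise
  clean_mean <- Reduce(`+`, lapply(wins, function(w) clean_f$values[, w])) / 8
  resid_avg <- avg$values - clean_mean
  in_var <- mean(vapply(wins, function(w) {
    mean((noisy_f$values[, w] - clean_f$values[, w])^2)
  }, numeric(1)))
  ratio <- sd(resid_avg) / sqrt(in_var / 8)
  expect_lt(abs(ratio - 1), 0.2)
  expect_error(signal_average(make_test_recording(n_beats = 1)), ">= 2")
})
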