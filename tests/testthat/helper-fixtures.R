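## Shared fixtures, built once per test run and cached (BEM assembly is the
## expensive part).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## default-geometry mesh pair (162 + 162 nodes)
fix_meshes <- function() fixture("meshes", function() {
  generate_concentric_meshes(2, 2, 30, c(100, 150, 80))
})

## transfer matrix on the default geometry
fix_forward <- function() fixture("forward", function() {
  m <- fix_meshes()
  build_transfer_matrix(m$epi, m$torso)
})

## clean (noise-free) synthetic dataset at study scale
fix_clean_dataset <- function() fixture("clean_dataset", function() {
  cfg <- fix_clean_config()
  m <- fix_meshes()
  act <- simulate_activation(m$epi, cfg$pacing_node, cfg$velocity_mm_per_ms)
  epi_rec <- simulate_epicardial_beats(act, cfg$template, cfg$n_beats,
                                       cfg$fs_hz, cfg$jitter_ms, seed = cfg$seed)
  torso_rec <- generate_torso_recording(fix_forward(), epi_rec, cfg$noise)
  list(epi = m$epi, torso = m$torso, act = act, epi_rec = epi_rec,
       torso_rec = torso_rec, forward = fix_forward())
})

fix_clean_config <- function() {
  study_config(noise = noise_spec(line_amp_mV = 0, white_sd_mV = 0,
                                  drift_amp_mV = 0),
               jitter_ms = 0, seed = 11, variants = "RAW")
}

## seeded noisy dataset at study scale (generator defaults)
fix_noisy_dataset <- function() fixture("noisy_dataset", function() {
  cfg <- study_config(seed = 11, variants = "RAW")
  m <- fix_meshes()
  act <- simulate_activation(m$epi, cfg$pacing_node, cfg$velocity_mm_per_ms)
  epi_rec <- simulate_epicardial_beats(act, cfg$template, cfg$n_beats,
                                       cfg$fs_hz, cfg$jitter_ms, seed = cfg$seed)
  noise <- cfg$noise
  noise$seed <- cfg$seed + 1L
  torso_rec <- generate_torso_recording(fix_forward(), epi_rec, noise)
  list(epi = m$epi, torso = m$torso, act = act, epi_rec = epi_rec,
       torso_rec = torso_rec, forward = fix_forward())
})

## study datasets are expensive (BEM assembly); pipeline tests run their
## configs against the shared cached dataset
fix_noisy_dataset_for_config <- function(cfg) fix_noisy_dataset()

## small multi-beat recording with known segmentation, for filter tests:
## biphasic beats + optional contaminants, fs 1000, 5 beats of 700 ms
make_test_recording <- function(n_leads = 4, n_beats = 5, fs = 1000,
                                line = 0, white = 0, drift = 0, seed = 42,
                                tmpl = beat_template()) {
  act <- activation_map(seq(0, 12, length.out = n_leads))
  rec <- simulate_epicardial_beats(act, tmpl, n_beats, fs, jitter_ms = 0)
  n <- ncol(rec$values)
  t_s <- (seq_len(n) - 1) / fs
  vals <- rec$values
  withr::with_seed(seed, {
    if (line > 0) {
      for (i in seq_len(n_leads)) {
        vals[i, ] <- vals[i, ] + line * sin(2 * pi * 50 * t_s + runif(1, 0, 2 * pi))
      }
    }
    if (white > 0) vals <- vals + matrix(rnorm(length(vals), 0, white), n_leads)
    if (drift > 0) {
      for (i in seq_len(n_leads)) {
        vals[i, ] <- vals[i, ] + drift * sin(2 * pi * 0.12 * t_s + runif(1, 0, 2 * pi))
      }
    }
  })
  potential_recording(vals, fs, segmentation = rec$segmentation)
}

## beats with exactly compact support (triangular "QRS" pulses, zero
## everywhere else), for tests that need the isoelectric windows to carry
## no waveform energy at all
make_square_beat_recording <- function(n_leads = 2, n_beats = 5, fs = 1000,
                                       cycle = 700) {
  n <- n_beats * cycle
  vals <- matrix(0, n_leads, n)
  onsets <- (seq_len(n_beats) - 1L) * cycle + 1L
  pulse <- c(seq(0, 5, length.out = 40), seq(5, -5, length.out = 40),
             seq(-5, 0, length.out = 40))
  for (b in seq_len(n_beats)) {
    for (i in seq_len(n_leads)) {
      vals[i, onsets[b] + 100 + seq_along(pulse)] <- pulse
    }
  }
  seg <- beat_segmentation(onset = onsets,
                           qrs_on = onsets + 100L,
                           qrs_off = onsets + 100L + length(pulse) + 1L,
                           iso_on = onsets + 60L, iso_len = 20L,
                           qrst_on = onsets + 100L,
                           qrst_off = onsets + 100L + length(pulse) + 1L)
  potential_recording(vals, fs, segmentation = seg)
}

## the classic severely ill-conditioned 1D image-restoration test problem
shaw_problem <- function(n = 32) {
  h <- pi / n
  s <- -pi / 2 + (seq_len(n) - 0.5) * h
  A <- outer(s, s, function(si, sj) {
    u <- pi * (sin(si) + sin(sj))
    k <- ifelse(abs(u) < 1e-12, 1, (sin(u) / u)^2)
    h * (cos(si) + cos(sj))^2 * k
  })
  x <- 2 * exp(-6 * (s - 0.8)^2) + exp(-2 * (s + 0.5)^2)
  list(A = A, x = x, y = as.vector(A %*% x))
}

## orthogonal-factor matrix with prescribed singular values
matrix_with_spectrum <- function(d, seed = 1) {
  withr::with_seed(seed, {
    n <- length(d)
    Q1 <- qr.Q(qr(matrix(rnorm(n * n), n)))
    Q2 <- qr.Q(qr(matrix(rnorm(n * n), n)))
    Q1 %*% diag(d) %*% t(Q2)
  })
}
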