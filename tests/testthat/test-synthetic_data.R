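test_that("concentric mesh generation gives closed icospheres with expected node counts", {
  m <- generate_concentric_meshes(2, 2, 30, c(100, 150, 80))
  expect_equal(nrow(m$epi$nodes), 10 * 4^2 + 2)     # 162
  expect_equal(nrow(m$torso$nodes), 10 * 4^2 + 2)
  expect_true(mesh_is_closed(m$epi))
  expect_true(mesh_is_closed(m$torso))
})

test_that("convex mesh triangles are wound outward", {
  m <- generate_concentric_meshes(1, 1, 30, c(100, 150, 80))
  for (mesh in m) {
    nrm <- ecgibench:::triangle_normals_raw(mesh)
    cent <- (mesh$nodes[mesh$triangles[, 1], ] +
             mesh$nodes[mesh$triangles[, 2], ] +
             mesh$nodes[mesh$triangles[, 3], ]) / 3
    expect_true(all(rowSums(nrm * cent) > 0))
  }
})

test_that("an epicardium not enclosed by the torso is rejected", {
  expect_error(generate_concentric_meshes(2, 2, 120, c(100, 150, 80)),
               "not enclosed")
  expect_error(generate_concentric_meshes(0, 2, 30, c(100, 150, 80)),
               "subdivision")
})

test_that("simulated activation is zero at the pacing site and scales with velocity", {
  epi <- fix_meshes()$epi
  a1 <- simulate_activation(epi, 5, 1)
  a2 <- simulate_activation(epi, 5, 2)
  expect_equal(a1$times_ms[5], 0)
  expect_equal(a1$times_ms, 2 * a2$times_ms)
  expect_equal(min(a1$times_ms), 0)
})

test_that("graph geodesics approximate great-circle distance to the antipode", {
  s <- icosphere(3, 40)
  pacing <- which.max(s$nodes[, 3])         # north pole
  a <- simulate_activation(s, pacing, 1)
  antipode <- which.min(s$nodes[, 3])
  ## edge-graph paths run along chords, so they can undercut the arc length
  ## slightly and overshoot it by the graph-metric anisotropy
  expected <- pi * 40
  tol <- mean(mesh_edge_lengths(s)) + 0.05 * expected
  expect_lt(abs(a$times_ms[antipode] - expected), tol)
})

test_that("disconnected meshes are reported with unreachable nodes", {
  s1 <- icosphere(1, 10)
  s2 <- icosphere(1, 10)
  s2$nodes <- s2$nodes + 100
  m <- surface_mesh(rbind(s1$nodes, s2$nodes),
                    rbind(s1$triangles, s2$triangles + nrow(s1$nodes)))
  expect_error(simulate_activation(m, 1, 1), "unreachable")
})

test_that("beat trains are pure time shifts of the template", {
  act <- activation_map(c(0, 5, 13, 27))
  tmpl <- beat_template()
  rec <- simulate_epicardial_beats(act, tmpl, n_beats = 1, fs_hz = 1000,
                                   jitter_ms = 0)
  ## min-dV/dt time differences reproduce activation time differences
  seg <- rec$segmentation
  win <- seg$qrs_on[1]:seg$qrs_off[1]
  at <- activation_times_min_dvdt(rec$values[, win, drop = FALSE], 1000)$times_ms
  expect_equal(at - at[1], act$times_ms - act$times_ms[1], tolerance = 1e-9)
})

test_that("zero-jitter beats repeat sample-for-sample and carry the stated amplitude", {
  act <- activation_map(c(0, 5, 13, 27))
  tmpl <- beat_template(rs_amplitude_mV = 10)
  rec <- simulate_epicardial_beats(act, tmpl, n_beats = 5, fs_hz = 1000,
                                   jitter_ms = 0)
  seg <- rec$segmentation
  cyc <- seg$onset[2] - seg$onset[1]
  b1 <- rec$values[, seg$onset[1]:(seg$onset[2] - 1)]
  for (b in 2:5) {
    expect_identical(b1, rec$values[, seg$onset[b]:(seg$onset[b] + cyc - 1)])
  }
  pp <- apply(rec$values, 1, function(v) diff(range(v)))
  expect_true(all(abs(pp - 10) / 10 < 0.01))
})

test_that("inconsistent beat timing is rejected", {
  act <- activation_map(c(0, 2000))   # shifts QRS beyond the cycle
  expect_error(simulate_epicardial_beats(act, beat_template(), 2, 1000, 0),
               "cycle")
  expect_error(simulate_epicardial_beats(activation_map(0), beat_template(),
                                         2, fs_hz = 100, jitter_ms = 0),
               "frequency content")
})

test_that("torso projection is exact when all noise amplitudes are zero", {
  ds <- fix_clean_dataset()
  expect_equal(ds$torso_rec$values,
               unname(ds$forward$A %*% ds$epi_rec$values),
               tolerance = 1e-12)
  expect_equal(ds$torso_rec$segmentation, ds$epi_rec$segmentation)
})

test_that("noise generation is a pure function of the spec seed", {
  ds <- fix_clean_dataset()
  ns <- noise_spec(seed = 99)
  y1 <- generate_torso_recording(ds$forward, ds$epi_rec, ns)
  y2 <- generate_torso_recording(ds$forward, ds$epi_rec, ns)
  expect_identical(y1$values, y2$values)
  y3 <- generate_torso_recording(ds$forward, ds$epi_rec, noise_spec(seed = 100))
  expect_gt(max(abs(y1$values - y3$values)), 0)
})

test_that("realized white-noise SD matches the spec within Monte-Carlo tolerance", {
  ds <- fix_clean_dataset()
  ns <- noise_spec(line_amp_mV = 0, drift_amp_mV = 0, white_sd_mV = 0.05,
                   seed = 5)
  y <- generate_torso_recording(ds$forward, ds$epi_rec, ns)
  resid <- y$values - ds$torso_rec$values
  sds <- apply(resid, 1, sd)
  expect_true(all(abs(sds - 0.05) / 0.05 < 0.05))
})

test_that("noise component variances add up (power accounting)", {
  ## >= 10 s record; enough leads/cycles that the cross-covariances between
  ## the (independently drawn) components average out below the tolerance
  act <- activation_map(seq(0, 10, length.out = 12))
  epi <- simulate_epicardial_beats(act, beat_template(), n_beats = 30,
                                   fs_hz = 1000, jitter_ms = 0)
  fwd <- forward_model(diag(12))
  clean <- generate_torso_recording(fwd, epi,
                                    noise_spec(line_amp_mV = 0, white_sd_mV = 0,
                                               drift_amp_mV = 0))
  one <- function(ns) {
    mean(apply(generate_torso_recording(fwd, epi, ns)$values - clean$values,
               1, stats::var))
  }
  v_line <- one(noise_spec(white_sd_mV = 0, drift_amp_mV = 0, seed = 2))
  v_white <- one(noise_spec(line_amp_mV = 0, drift_amp_mV = 0, seed = 2))
  v_drift <- one(noise_spec(line_amp_mV = 0, white_sd_mV = 0, seed = 2))
  v_all <- one(noise_spec(seed = 2))
  expect_lt(abs(v_all - (v_line + v_white + v_drift)) / v_all, 0.05)
})

test_that("noise components sit in their design bands", {
  act <- activation_map(0)
  epi <- simulate_epicardial_beats(act, beat_template(), n_beats = 15,
                                   fs_hz = 1000, jitter_ms = 0)
  fwd <- forward_model(diag(1))
  clean <- generate_torso_recording(fwd, epi, noise_spec(line_amp_mV = 0,
                                                         white_sd_mV = 0,
                                                         drift_amp_mV = 0))
  n <- ncol(epi$values)
  f <- (seq_len(n) - 1) * 1000 / n
  ## line: spectral peak at 50 Hz within one bin
  line <- generate_torso_recording(fwd, epi,
                                   noise_spec(white_sd_mV = 0, drift_amp_mV = 0,
                                              harmonics = 0, seed = 3))
  spec <- Mod(fft(line$values[1, ] - clean$values[1, ]))[seq_len(n %/% 2)]
  expect_lt(abs(f[which.max(spec)] - 50), 1000 / n + 1e-9)
  ## drift: >= 99% of energy below 0.5 Hz
  drift <- generate_torso_recording(fwd, epi,
                                    noise_spec(line_amp_mV = 0, white_sd_mV = 0,
                                               seed = 3))
  spec_d <- Mod(fft(drift$values[1, ] - clean$values[1, ]))[seq_len(n %/% 2)]^2
  expect_gt(sum(spec_d[f[seq_len(n %/% 2)] <= 0.5]) / sum(spec_d), 0.99)
})

test_that("noise spec validates its invariants", {
  expect_error(noise_spec(line_freq_hz = 45), "50 or 60")
  expect_error(noise_spec(line_amp_mV = -1), ">= 0")
  expect_error(noise_spec(drift_freq_hz = c(0.1, 2)), "0.5 Hz")
  expect_error(generate_torso_recording(forward_model(diag(5)),
                                        simulate_epicardial_beats(
                                          activation_map(c(0, 3)),
                                          beat_template(), 1, 1000, 0),
                                        noise_spec()),
               "does not match")
})
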