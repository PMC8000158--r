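## Signal-quality and reconstruction-accuracy metrics: SNR-HF, baseline
## shift, electrogram amplitude and morphology, activation times, pacing
## site localization.

#' High-frequency signal-to-noise ratio (dB)
#'
#' The recording first gets a simple baseline correction (BDR1). A
#' root-mean-square-across-leads voltage curve is computed per sample; for
#' each beat the QRS amplitude is the peak of that curve inside the QRS
#' window and the noise amplitude is its RMS over a pre-QRS window
#' (`noise_win_ms`, 40 ms for the 50 Hz dialect / 34 ms for 60 Hz). SNR-HF
#' is 20*log10 of the mean (over beats) QRS/noise ratio.
#'
#' @param rec segmented `potential_recording`.
#' @param noise_win_ms pre-QRS noise window length (ms).
#' @param qrs_stat "peak" (default) or "mean" of the RMS curve over the QRS.
#' @param cap dB value reported when the noise amplitude is zero.
#' @return SNR-HF in dB.
#' @export
snr_hf <- function(rec, noise_win_ms = 40, qrs_stat = c("peak", "mean"),
                   cap = 300) {
  qrs_stat <- match.arg(qrs_stat)
  seg <- rec$segmentation
  need_segmentation(seg, "snr_hf")
  rec <- apply_bdr(rec, "BDR1")
  good <- !rec$bad_leads
  rmsv <- sqrt(colMeans(rec$values[good, , drop = FALSE]^2))
  nwin <- ms_to_samples(noise_win_ms, rec$fs_hz)
  ratios <- vapply(seg$beat, function(b) {
    qrs <- rmsv[seg_window(seg, b, "qrs")]
    q <- if (qrs_stat == "peak") max(qrs) else mean(qrs)
    lo <- max(1L, seg$qrs_on[seg$beat == b] - nwin)
    noise <- sqrt(mean(rmsv[lo:(seg$qrs_on[seg$beat == b] - 1L)]^2))
    q / noise
  }, numeric(1))
  if (any(!is.finite(ratios))) {
    warnf("snr_hf: zero noise amplitude; capping at %g dB", cap)
    return(cap)
  }
  20 * log10(mean(ratios))
}

#' Baseline shift (mV)
#'
#' Deviation of the pre-QRS isoelectric point: per lead and beat, the mean
#' over the isoelectric window; the metric is the mean absolute deviation
#' over leads and beats.
#'
#' @param rec segmented `potential_recording`.
#' @return baseline shift in mV.
#' @export
baseline_shift <- function(rec) {
  seg <- rec$segmentation
  need_segmentation(seg, "baseline_shift")
  good <- !rec$bad_leads
  devs <- sapply(seg$beat, function(b) {
    rowMeans(rec$values[good, seg_window(seg, b, "iso"), drop = FALSE])
  })
  mean(abs(devs))
}

#' Electrogram amplitude metrics
#'
#' Electrogram amplitude of a recording is the mean over leads of the
#' peak-to-peak amplitude within the analysis window. Returns the absolute
#' difference of the two amplitudes and the relative difference normalized
#' by the maximum recorded (truth) peak-to-peak amplitude.
#'
#' @param recon,truth leads x samples matrices (matched leads and windows).
#' @return list(abs_diff_mV=, rel_diff=).
#' @export
amplitude_metrics <- function(recon, truth) {
  if (!all(dim(recon) == dim(truth))) stopf("recon/truth dimensions differ")
  pp <- function(X) apply(X, 1, function(v) diff(range(v)))
  pp_r <- pp(recon); pp_t <- pp(truth)
  abs_diff <- abs(mean(pp_r) - mean(pp_t))
  list(abs_diff_mV = abs_diff, rel_diff = abs_diff / max(pp_t))
}

#' Per-lead QRS Pearson correlation
#'
#' @param recon,truth leads x samples matrices over the QRS window.
#' @return list(per_lead=, median=); zero-variance leads are excluded (NA in
#'   `per_lead`) with a message.
#' @export
qrs_correlation <- function(recon, truth) {
  if (!all(dim(recon) == dim(truth))) stopf("recon/truth dimensions differ")
  if (ncol(truth) < 3) stopf("need >= 3 samples for correlation")
  r <- vapply(seq_len(nrow(truth)), function(i) {
    if (sd(recon[i, ]) == 0 || sd(truth[i, ]) == 0) NA_real_
    else cor(recon[i, ], truth[i, ])
  }, numeric(1))
  if (anyNA(r)) message(sprintf("qrs_correlation: %d zero-variance leads excluded", sum(is.na(r))))
  list(per_lead = r, median = median(r, na.rm = TRUE))
}

#' Activation times by minimum derivative
#'
#' Per lead, the time (ms, relative to the window start) of the minimum
#' central-difference derivative within the QRS window. Flat leads are
#' excluded (NA).
#'
#' @param egms leads x samples matrix (mV).
#' @param fs_hz sampling rate.
#' @return an `activation_map` (times in ms, NA on flat leads).
#' @export
activation_times_min_dvdt <- function(egms, fs_hz) {
  n <- ncol(egms)
  if (n < 3) stopf("window too short for derivative")
  t_idx <- vapply(seq_len(nrow(egms)), function(i) {
    v <- egms[i, ]
    if (diff(range(v)) == 0) return(NA_real_)
    d <- (v[3:n] - v[1:(n - 2)]) / 2      # central difference
    which.min(d) + 1                       # index within window
  }, numeric(1))
  if (anyNA(t_idx)) message(sprintf("activation_times_min_dvdt: %d flat leads excluded", sum(is.na(t_idx))))
  structure(list(times_ms = (t_idx - 1) * 1000 / fs_hz, mesh = NULL,
                 pacing_site = NULL),
            class = "activation_map")
}

#' Spatio-temporal activation times
#'
#' Blends per-lead minimum-derivative candidate times with pairwise delay
#' estimates between mesh-adjacent leads (obtained by cross-correlating
#' their windowed derivatives), fused by regularized least squares:
#' minimize sum_i w_c (t_i - c_i)^2 + sum_(ij in E) (t_i - t_j - d_ij)^2.
#' This follows the published one-sentence description of the approach and
#' is an interpretation, not a reproduction, of the referenced algorithm.
#' Nodes isolated in the adjacency fall back to their candidate times.
#'
#' @param egms leads x samples matrix over the QRS window (one lead per mesh
#'   node).
#' @param mesh `surface_mesh` supplying the adjacency (leads = nodes).
#' @param fs_hz sampling rate.
#' @param candidate_weight weight w_c of the candidate (min-dV/dt) term.
#' @param max_lag_ms delay search range for the cross-correlation.
#' @return an `activation_map` (times in ms from window start, clamped to
#'   the window).
#' @export
activation_times_spatiotemporal <- function(egms, mesh, fs_hz,
                                            candidate_weight = 0.1,
                                            max_lag_ms = 40) {
  n_leads <- nrow(egms)
  if (n_leads != nrow(mesh$nodes)) stopf("one lead per mesh node required")
  cand <- activation_times_min_dvdt(egms, fs_hz)$times_ms
  cand[is.na(cand)] <- mean(cand, na.rm = TRUE)
  n <- ncol(egms)
  D <- (egms[, 3:n, drop = FALSE] - egms[, 1:(n - 2), drop = FALSE]) / 2
  edges <- mesh_edges(mesh)
  max_lag <- ms_to_samples(max_lag_ms, fs_hz)
  lags <- -max_lag:max_lag
  delay <- vapply(seq_len(nrow(edges)), function(k) {
    a <- D[edges[k, 1], ]; b <- D[edges[k, 2], ]
    cc <- vapply(lags, function(L) {
      if (L >= 0) sum(a[(1 + L):length(a)] * b[1:(length(b) - L)])
      else sum(a[1:(length(a) + L)] * b[(1 - L):length(b)])
    }, numeric(1))
    lags[which.max(cc)] * 1000 / fs_hz   # t_a - t_b estimate (ms)
  }, numeric(1))
  ## normal equations of the blended least squares
  wc <- candidate_weight
  M <- diag(wc, n_leads)
  rhs <- wc * cand
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    M[i, i] <- M[i, i] + 1; M[j, j] <- M[j, j] + 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    rhs[i] <- rhs[i] + delay[k]
    rhs[j] <- rhs[j] - delay[k]
  }
  t_ms <- solve(M, rhs)
  t_ms <- pmin(pmax(t_ms, 0), (n - 1) * 1000 / fs_hz)
  structure(list(times_ms = as.vector(t_ms), mesh = mesh, pacing_site = NULL),
            class = "activation_map")
}

#' Activation-map comparison
#'
#' @param recon_map,truth_map `activation_map`s on a common node set.
#' @return list(pearson_r=, mae_ms=) over nodes finite in both maps.
#' @export
map_metrics <- function(recon_map, truth_map) {
  a <- recon_map$times_ms; b <- truth_map$times_ms
  if (length(a) != length(b)) stopf("maps differ in node count")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stopf("fewer than 3 common nodes")
  list(pearson_r = cor(a[ok], b[ok]), mae_ms = mean(abs(a[ok] - b[ok])))
}

#' Automated pacing-site localization
#'
#' Among nodes whose neighbors' median activation time lies within
#' `neighbor_window_ms` of the node's own time (rejecting isolated
#' activation-marker artefacts), picks the earliest; ties are resolved by
#' averaging the tied nodes' coordinates. If no node passes the neighbor
#' criterion the global minimum is returned with attribute `warning_flag`.
#'
#' @param map an `activation_map`.
#' @param mesh `surface_mesh` (defaults to the map's mesh); neighbor set is
#'   the 1-ring adjacency.
#' @param neighbor_window_ms neighbor-median acceptance window (30 ms).
#' @return length-3 coordinates of the estimated pacing site.
#' @export
locate_pacing_site <- function(map, mesh = map$mesh, neighbor_window_ms = 30) {
  if (is.null(mesh)) stopf("mesh required")
  t_ms <- map$times_ms
  adj <- mesh_adjacency(mesh)
  ok <- vapply(seq_along(t_ms), function(i) {
    nb <- adj[[i]]
    length(nb) > 0 &&
      abs(median(t_ms[nb]) - t_ms[i]) <= neighbor_window_ms
  }, logical(1))
  flag <- FALSE
  if (!any(ok)) {
    warnf("locate_pacing_site: no node passed the neighbor criterion; using global minimum")
    ok <- rep(TRUE, length(t_ms))
    flag <- TRUE
  }
  tmin <- min(t_ms[ok])
  tied <- which(ok & t_ms == tmin)
  site <- colMeans(mesh$nodes[tied, , drop = FALSE])
  structure(site, warning_flag = flag)
}

#' Pacing-site localization error (mm)
#'
#' @param site_recon,site_truth length-3 coordinates in the same frame.
#' @return Euclidean distance (mm).
#' @export
localization_error <- function(site_recon, site_truth) {
  sqrt(sum((as.numeric(site_recon) - as.numeric(site_truth))^2))
}
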