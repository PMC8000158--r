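## Study orchestration: build (or accept) a synthetic torso-tank dataset,
## run processing variants through reconstruction and evaluation, and emit
## a tidy long-format results table.

#' Study configuration
#'
#' Defaults describe the desk-scale synthetic torso-tank study: icosphere
#' "sock" of 162 nodes at 30 mm (inter-node spacing ~8 mm), ellipsoidal tank
#' (100, 150, 80) mm at 162 nodes, right-ventricular-like single-site pacing
#' at 0.8 mm/ms, 5 beats at 700 ms cycle, 1000 Hz sampling, 50 Hz dialect.
#'
#' @param epi_subdivisions,torso_subdivisions,epi_radius_mm,torso_radii_mm
#'   mesh parameters (see [generate_concentric_meshes()]).
#' @param pacing_node epicardial pacing node index.
#' @param velocity_mm_per_ms conduction velocity.
#' @param n_beats,fs_hz,jitter_ms beat train parameters.
#' @param template a `beat_template`.
#' @param noise a `noise_spec` (set amplitudes to 0 for a clean study).
#' @param seed master RNG seed (mandatory); the noise spec's seed is derived
#'   from it.
#' @param variants character vector of method IDs (default: all 49).
#' @param window analysis window for reconstruction ("qrst" or "qrs").
#' @param lambda_n_points,lambda_span L-curve grid parameters.
#' @param electrode_nodes optional subset of torso nodes used as electrodes.
#' @return object of class `study_config`.
#' @export
study_config <- function(epi_subdivisions = 2, torso_subdivisions = 2,
                         epi_radius_mm = 30, torso_radii_mm = c(100, 150, 80),
                         pacing_node = 1, velocity_mm_per_ms = 0.8,
                         n_beats = 5, fs_hz = 1000, jitter_ms = 2,
                         template = beat_template(),
                         noise = noise_spec(), seed = 1,
                         variants = NULL, window = "qrst",
                         lambda_n_points = 200, lambda_span = c(1e-8, 1e2),
                         electrode_nodes = NULL) {
  if (is.null(seed)) stopf("seed is mandatory when generating data")
  variants <- variants %||% vapply(enumerate_methods(noise$line_freq_hz),
                                   `[[`, character(1), "id")
  valid <- vapply(enumerate_methods(noise$line_freq_hz), `[[`, character(1), "id")
  if (!all(variants %in% valid)) {
    stopf("unknown variant IDs: %s", paste(setdiff(variants, valid), collapse = ", "))
  }
  structure(list(epi_subdivisions = epi_subdivisions,
                 torso_subdivisions = torso_subdivisions,
                 epi_radius_mm = epi_radius_mm, torso_radii_mm = torso_radii_mm,
                 pacing_node = pacing_node,
                 velocity_mm_per_ms = velocity_mm_per_ms,
                 n_beats = n_beats, fs_hz = fs_hz, jitter_ms = jitter_ms,
                 template = template, noise = noise, seed = seed,
                 variants = variants, window = window,
                 lambda_n_points = lambda_n_points, lambda_span = lambda_span,
                 electrode_nodes = electrode_nodes),
            class = "study_config")
}

#' Generate the synthetic dataset a study runs on
#'
#' @param config a `study_config`.
#' @return list with `epi`, `torso` (meshes), `act` (activation map),
#'   `epi_rec`, `torso_rec` (recordings), `forward` (forward model).
#' @export
build_study_dataset <- function(config) {
  meshes <- generate_concentric_meshes(config$epi_subdivisions,
                                       config$torso_subdivisions,
                                       config$epi_radius_mm,
                                       config$torso_radii_mm)
  act <- simulate_activation(meshes$epi, config$pacing_node,
                             config$velocity_mm_per_ms)
  iso_ms <- if (config$noise$line_freq_hz == 60) 17 else 20
  epi_rec <- simulate_epicardial_beats(act, config$template, config$n_beats,
                                       config$fs_hz, config$jitter_ms,
                                       iso_len_ms = iso_ms,
                                       seed = config$seed)
  forward <- build_transfer_matrix(meshes$epi, meshes$torso)
  if (!is.null(config$electrode_nodes)) {
    forward <- sample_electrode_rows(forward, config$electrode_nodes)
  }
  noise <- config$noise
  noise$seed <- config$seed + 1L
  torso_rec <- generate_torso_recording(forward, epi_rec, noise)
  list(epi = meshes$epi, torso = meshes$torso, act = act,
       epi_rec = epi_rec, torso_rec = torso_rec, forward = forward)
}

## windows of the recon beat relative to its analysis window
relative_qrs <- function(seg, b, window) {
  full <- seg_window(seg, b, window)
  qrs <- seg_window(seg, b, "qrs")
  match(qrs, full)
}

#' Run the full processing-variant study
#'
#' For every requested variant: filter the torso recording, reconstruct each
#' beat (Tikhonov + median L-curve lambda), and evaluate electrogram and
#' activation-map accuracy against the simulated epicardial recording. The
#' signal-averaged variant produces a single beat that is compared against
#' every unaveraged truth beat. Variant failures are recorded and skipped.
#'
#' @param config a `study_config`.
#' @param dataset optional pre-built dataset (see [build_study_dataset()]).
#' @param verbose print per-variant progress.
#' @return tidy data frame (variant, category, beat, metric, value) of class
#'   `evaluation_report`, with the config and dataset attached as
#'   attributes; `attr(,"failures")` lists failed variants.
#' @export
run_study <- function(config, dataset = NULL, verbose = FALSE) {
  dataset <- dataset %||% build_study_dataset(config)
  ds <- dataset
  A <- with_svd(ds$forward$A)
  fwd <- ds$forward; fwd$A <- A
  grid <- lambda_grid(A, config$lambda_n_points, config$lambda_span)
  noise_win <- if (config$noise$line_freq_hz == 60) 34 else 40
  tseg <- ds$epi_rec$segmentation
  truth_maps <- lapply(tseg$beat, function(b) {
    activation_times_min_dvdt(ds$epi_rec$values[, seg_window(tseg, b, "qrs"),
                                                drop = FALSE], config$fs_hz)
  })
  truth_site <- ds$epi$nodes[config$pacing_node, ]
  rows <- list()
  failures <- character(0)
  add <- function(variant, category, beat, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, category = category, beat = beat,
      metric = metric, value = as.numeric(value))
  }
  for (vid in config$variants) {
    spec <- filter_spec(vid, config$noise$line_freq_hz)
    t0 <- Sys.time()
    ok <- tryCatch({
      filt <- apply_method(ds$torso_rec, spec)
      add(vid, spec$category, NA, "snr_hf_dB", snr_hf(filt, noise_win))
      add(vid, spec$category, NA, "baseline_shift_mV", baseline_shift(filt))
      sol <- reconstruct(fwd, filt, window = config$window, grid = grid)
      rseg <- filt$segmentation
      for (k in seq_along(sol$beats)) {
        bt <- sol$beats[[k]]
        truth_beats <- if (spec$category == "SA") tseg$beat else tseg$beat[k]
        qrs_rel_r <- relative_qrs(rseg, rseg$beat[k], config$window)
        for (b in truth_beats) {
          tw <- seg_window(tseg, b, config$window)
          truth <- ds$epi_rec$values[, tw, drop = FALSE]
          nuse <- min(ncol(truth), ncol(bt$X))
          am <- amplitude_metrics(bt$X[, seq_len(nuse), drop = FALSE],
                                  truth[, seq_len(nuse), drop = FALSE])
          qrs_rel_t <- relative_qrs(tseg, b, config$window)
          nq <- min(length(qrs_rel_r), length(qrs_rel_t))
          qc <- qrs_correlation(bt$X[, qrs_rel_r[seq_len(nq)], drop = FALSE],
                                truth[, qrs_rel_t[seq_len(nq)], drop = FALSE])
          rmap <- activation_times_spatiotemporal(
            bt$X[, qrs_rel_r[seq_len(nq)], drop = FALSE], ds$epi, config$fs_hz)
          tmap <- truth_maps[[b]]
          mm <- map_metrics(rmap, tmap)
          site <- locate_pacing_site(rmap, ds$epi)
          add(vid, spec$category, b, "lambda_median", bt$lambda_median)
          add(vid, spec$category, b, "amp_abs_diff_mV", am$abs_diff_mV)
          add(vid, spec$category, b, "amp_rel_diff", am$rel_diff)
          add(vid, spec$category, b, "qrs_corr_median", qc$median)
          add(vid, spec$category, b, "at_corr", mm$pearson_r)
          add(vid, spec$category, b, "at_mae_ms", mm$mae_ms)
          add(vid, spec$category, b, "le_mm", localization_error(site, truth_site))
        }
      }
      TRUE
    }, error = function(e) {
      warnf("variant %s failed: %s", vid, conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- c(failures, vid)
    if (verbose) {
      message(sprintf("%-12s %s  (%.1f s)", vid, if (ok) "ok" else "FAILED",
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("evaluation_report", "data.frame")
  attr(report, "config") <- config
  attr(report, "dataset") <- dataset
  attr(report, "failures") <- failures
  report
}

#' Aggregate an evaluation report
#'
#' @param report an `evaluation_report`.
#' @return data frame of mean, SD and median per variant x metric across
#'   beats.
#' @export
summarize_report <- function(report) {
  agg <- aggregate(value ~ variant + category + metric, data = report,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       median = median(v)))
  out <- cbind(agg[, c("variant", "category", "metric")],
               as.data.frame(agg$value))
  out$sd[is.na(out$sd)] <- 0
  out[order(out$metric, out$variant), ]
}

#' Write study outputs
#'
#' Writes the tidy results table (`results.csv`), the aggregate summary
#' (`summary.csv`) and a provenance sidecar (`provenance.json`: config,
#' config hash, seed, package version).
#'
#' @param report an `evaluation_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report, file.path(outdir, "results.csv"), row.names = FALSE)
  write.csv(summarize_report(report), file.path(outdir, "summary.csv"),
            row.names = FALSE)
  config <- attr(report, "config")
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
  }
  cfg_plain <- strip_classes(config)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  prov <- list(config = jsonlite::fromJSON(cfg_json),
               config_md5 = unname(tools::md5sum(tmp)),
               seed = config$seed,
               failures = attr(report, "failures"),
               package_version = as.character(packageVersion("ecgibench")))
  unlink(tmp)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
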