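#!/usr/bin/env Rscript

## Build the synthetic torso-tank dataset the study runs on: concentric
## epicardial/torso surfaces, a single-site paced activation sequence,
## multi-beat epicardial electrograms, the BEM transfer matrix, and the
## noise-contaminated torso recording. Everything is written under
## results/data/ in plain-text interchange formats so the later stages (and
## any external tool) can pick them up.

suppressPackageStartupMessages(library(ecgibench))

SEED <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- study_config(seed = SEED)
ds <- build_study_dataset(cfg)

message(sprintf("epicardial surface: %d nodes, mean inter-node spacing %.1f mm",
                nrow(ds$epi$nodes), mean(mesh_edge_lengths(ds$epi))))
message(sprintf("torso surface:      %d nodes, mean inter-node spacing %.1f mm",
                nrow(ds$torso$nodes), mean(mesh_edge_lengths(ds$torso))))
message(sprintf("activation: pacing node %d, spread %.0f-%.0f ms",
                cfg$pacing_node, min(ds$act$times_ms), max(ds$act$times_ms)))
message(sprintf("recordings: %d beats at %g Hz, %d epicardial / %d torso leads",
                cfg$n_beats, cfg$fs_hz,
                nrow(ds$epi_rec$values), nrow(ds$torso_rec$values)))
message(sprintf("forward matrix: %d x %d (rcond %.2g)",
                nrow(ds$forward$A), ncol(ds$forward$A), ds$forward$meta$rcond))

write_mesh_off(ds$epi, file.path(out, "epicardium.off"))
write_mesh_off(ds$torso, file.path(out, "torso.off"))
write_matrix_mm(ds$forward$A, file.path(out, "transfer_matrix.mtx"))
write_recording_csv(ds$epi_rec, file.path(out, "epicardial_recording.csv"))
write_recording_csv(ds$torso_rec, file.path(out, "torso_recording.csv"))
write_electrode_list(seq_len(nrow(ds$torso$nodes)),
                     file.path(out, "electrode_nodes.txt"))
writeLines(as.character(ds$act$times_ms), file.path(out, "activation_times_ms.txt"))

message("wrote results/data/{epicardium,torso}.off, transfer_matrix.mtx, ",
        "epicardial_recording.csv, torso_recording.csv (+ .json sidecars)")
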