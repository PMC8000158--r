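## Plain-text interchange formats: OFF meshes, CSV recordings (+ JSON
## sidecar), Matrix Market transfer matrices, electrode index lists.

#' Read / write a surface mesh in OFF format
#'
#' @param path file path.
#' @return `read_mesh_off`: a `surface_mesh`.
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stopf("%s: missing OFF header", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) {
    stopf("%s: truncated OFF file (expected %d vertex + %d face lines)", path, nv, nf)
  }
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- lines[(3 + nv):(2 + nv + nf)]
  faces <- t(vapply(seq_along(fl), function(i) {
    v <- scan(text = fl[i], quiet = TRUE)
    if (v[1] != 3) stopf("%s: face %d is not a triangle", path, i)
    v[2:4] + 1   # OFF is 0-based
  }, numeric(3)))
  surface_mesh(verts, faces)
}

#' @rdname read_mesh_off
#' @param mesh a `surface_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$nodes, 1, function(v) paste(sprintf("%.9g", v), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(f) paste(c(3, f), collapse = " ")), con)
  invisible(path)
}

#' Read / write a potential recording as CSV plus JSON sidecar
#'
#' The CSV holds one column per lead (header row of lead IDs) and one row
#' per sample, in mV. The sidecar `<path>.json` carries the sampling rate,
#' bad-lead mask and beat segmentation.
#'
#' @param path CSV file path.
#' @return `read_recording_csv`: a `potential_recording`.
#' @export
read_recording_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (any(!vapply(df, is.numeric, logical(1)))) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stopf("%s: non-numeric values in column '%s'", path, names(df)[bad])
  }
  if (anyNA(df)) {
    bad_row <- which(rowSums(is.na(df)) > 0)[1]
    stopf("%s: truncated or malformed data at row %d", path, bad_row)
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("missing sidecar %s", side)
  meta <- jsonlite::fromJSON(side)
  seg <- NULL
  if (!is.null(meta$segmentation) && length(meta$segmentation)) {
    s <- as.data.frame(meta$segmentation)
    seg <- beat_segmentation(s$onset, s$qrs_on, s$qrs_off, s$iso_on,
                             s$iso_len, s$qrst_on, s$qrst_off)
  }
  potential_recording(t(as.matrix(df)), meta$fs_hz, lead_ids = names(df),
                      bad_leads = as.logical(meta$bad_leads), segmentation = seg)
}

#' @rdname read_recording_csv
#' @param rec a `potential_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$values))
  names(df) <- rec$lead_ids
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz, bad_leads = rec$bad_leads,
               segmentation = if (is.null(rec$segmentation)) list() else
                 as.data.frame(unclass(rec$segmentation)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a transfer matrix in Matrix Market format
#'
#' @param path file path.
#' @return `read_matrix_mm`: a dense base matrix.
#' @export
read_matrix_mm <- function(path) {
  as.matrix(Matrix::readMM(path))
}

#' @rdname read_matrix_mm
#' @param A numeric matrix.
#' @export
write_matrix_mm <- function(A, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(A), "generalMatrix"),
                              "TsparseMatrix"), path)
  invisible(path)
}

#' Read / write an electrode index list
#'
#' One index per line; the file is 0-based (as conventional for exchange
#' with other tools), converted to/from R's 1-based indices.
#'
#' @param path file path.
#' @return `read_electrode_list`: integer vector of 1-based indices.
#' @export
read_electrode_list <- function(path) {
  as.integer(readLines(path)) + 1L
}

#' @rdname read_electrode_list
#' @param idx integer vector of 1-based indices.
#' @export
write_electrode_list <- function(idx, path) {
  writeLines(as.character(as.integer(idx) - 1L), path)
  invisible(path)
}
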