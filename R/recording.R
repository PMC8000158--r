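## Multi-lead potential recordings and beat segmentation.

#' Potential recording container
#'
#' Leads x samples potential matrix (mV) with sampling rate, lead IDs,
#' bad-lead mask and beat segmentation.
#'
#' @param values numeric leads x samples matrix (mV).
#' @param fs_hz sampling rate (Hz, > 0).
#' @param lead_ids character vector of lead identifiers.
#' @param bad_leads logical mask (TRUE = excluded from analysis).
#' @param segmentation a `beat_segmentation` data frame or NULL.
#' @return object of class `potential_recording`.
#' @export
potential_recording <- function(values, fs_hz, lead_ids = NULL,
                                bad_leads = NULL, segmentation = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (fs_hz <= 0) stopf("fs_hz must be > 0")
  nl <- nrow(values)
  lead_ids <- lead_ids %||% sprintf("L%03d", seq_len(nl))
  bad_leads <- bad_leads %||% rep(FALSE, nl)
  if (length(lead_ids) != nl || length(bad_leads) != nl) {
    stopf("lead_ids/bad_leads length must match lead count")
  }
  good <- values[!bad_leads, , drop = FALSE]
  if (length(good) && !all(is.finite(good))) {
    stopf("non-finite values on good leads")
  }
  if (!is.null(segmentation)) check_segmentation(segmentation, ncol(values))
  structure(list(values = values, fs_hz = fs_hz, lead_ids = lead_ids,
                 bad_leads = bad_leads, segmentation = segmentation),
            class = "potential_recording")
}

#' @export
print.potential_recording <- function(x, ...) {
  cat(sprintf("potential_recording: %d leads x %d samples @ %g Hz (%d beats, %d bad leads)\n",
              nrow(x$values), ncol(x$values), x$fs_hz,
              if (is.null(x$segmentation)) 0L else nrow(x$segmentation),
              sum(x$bad_leads)))
  invisible(x)
}

#' Beat segmentation table
#'
#' One row per beat: QRS onset/offset, the pre-QRS isoelectric window
#' (start + length) and the QRST window used for averaging, all in 1-based
#' sample indices.
#'
#' @param onset,qrs_on,qrs_off,iso_on,iso_len,qrst_on,qrst_off integer
#'   vectors, one element per beat.
#' @return data frame of class `beat_segmentation`.
#' @export
beat_segmentation <- function(onset, qrs_on, qrs_off, iso_on, iso_len,
                              qrst_on = qrs_on, qrst_off = qrs_off) {
  df <- data.frame(beat = seq_along(onset), onset = as.integer(onset),
                   qrs_on = as.integer(qrs_on), qrs_off = as.integer(qrs_off),
                   iso_on = as.integer(iso_on), iso_len = as.integer(iso_len),
                   qrst_on = as.integer(qrst_on), qrst_off = as.integer(qrst_off))
  class(df) <- c("beat_segmentation", "data.frame")
  df
}

check_segmentation <- function(seg, n_samples) {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$iso_on + seg$iso_len - 1L > seg$qrs_on)) {
    stopf("isoelectric window must end at or before QRS onset")
  }
  if (any(seg$qrs_on > seg$qrs_off) || any(seg$qrst_on > seg$qrst_off)) {
    stopf("windows must be non-empty and ordered")
  }
  if (is.unsorted(seg$onset, strictly = TRUE)) stopf("beats must be ordered")
  if (any(head(seg$qrst_off, -1) > tail(seg$onset, -1))) {
    stopf("beats must be non-overlapping")
  }
  if (any(seg$iso_on < 1L) || any(seg$qrst_off > n_samples)) {
    stopf("segmentation windows outside record length")
  }
  invisible(seg)
}

seg_window <- function(seg, beat, what = c("qrs", "qrst", "iso")) {
  what <- match.arg(what)
  row <- seg[seg$beat == beat, ]
  switch(what,
         qrs = row$qrs_on:row$qrs_off,
         qrst = row$qrst_on:row$qrst_off,
         iso = row$iso_on:(row$iso_on + row$iso_len - 1L))
}
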