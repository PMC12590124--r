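# Plain-text cohort container: one CSV matrix (trials x samples) per subject
# plus a JSON metadata sidecar. Doubles are written as "%.17g" so that a
# write/read cycle is bit-exact for float64.

#' Write a cohort to a directory of CSV matrices plus JSON metadata
#'
#' @param recordings List of [epoched_recording()] objects (or the `$recordings`
#'   element of [generate_cohort()] output).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(recordings, dir) {
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  stopifnot(all(vapply(recordings, inherits, TRUE, "epoched_recording")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(subjects = list())
  for (rec in recordings) {
    f <- file.path(dir, paste0(rec$subject_id, ".csv"))
    lines <- apply(rec$data, 1L, function(row)
      paste(sprintf("%.17g", row), collapse = ","))
    writeLines(lines, f)
    meta$subjects[[rec$subject_id]] <- list(
      file = basename(f), fs = rec$fs, group = rec$group,
      modality = rec$modality, times_ms = rec$times)
  }
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing per-subject CSV files and `cohort.json`.
#' @return List of [epoched_recording()] objects.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"))
  lapply(names(meta$subjects), function(id) {
    m <- meta$subjects[[id]]
    lines <- readLines(file.path(dir, m$file))
    data <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
    epoched_recording(data, fs = m$fs, times = unlist(m$times_ms),
                      subject_id = id, group = m$group, modality = m$modality)
  })
}
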