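#' EEG recording container
#'
#' An `eeg_recording` holds a channels-by-samples numeric matrix in microvolts
#' together with its sampling rate, unique channel labels, and an optional
#' disease-state label (`"calm"`, `"transitional"` or `"morbidity"`).
#'
#' @param data numeric matrix, one row per channel.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector of unique labels, one per row of
#'   `data`. Defaults to `ch1, ch2, ...`.
#' @param state optional state label, one of `"calm"`, `"transitional"`,
#'   `"morbidity"`, or `NA`.
#' @param subject_id optional identifier used when recordings from the same
#'   subject must stay on the same side of a train/test split.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, state = NA_character_,
                          subject_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  rec <- structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         state = as.character(state), subject_id = as.character(subject_id)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

eeg_states <- c("calm", "transitional", "morbidity")

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$data))
  if (!all(is.finite(rec$data))) stop("recording data must be finite")
  if (length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0)
    stop("fs must be a positive scalar")
  if (nrow(rec$data) < 1L) stop("need at least one channel")
  if (ncol(rec$data) < 2L) stop("need at least two samples")
  if (length(rec$channel_labels) != nrow(rec$data))
    stop("one channel label per data row required")
  if (anyDuplicated(rec$channel_labels))
    stop("channel labels must be unique")
  if (!is.na(rec$state) && !rec$state %in% eeg_states)
    stop("state must be one of: ", paste(eeg_states, collapse = ", "))
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.na(x$state)) cat("  state:", x$state, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

channel_index <- function(rec, channel) {
  if (is.numeric(channel)) {
    idx <- as.integer(channel)
    if (idx < 1L || idx > nrow(rec$data)) stop("channel index out of range")
    return(idx)
  }
  idx <- match(channel, rec$channel_labels)
  if (is.na(idx)) stop("unknown channel: ", channel)
  idx
}

#' Write an EEG recording to a TSV file
#'
#' The format is plain text: three header lines (`#fs`, `#channels`,
#' `#state`) followed by one tab-separated row of samples per channel, in
#' the order of `channel_labels`.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#fs\t", format(rec$fs, digits = 17)),
    paste0("#channels\t", paste(rec$channel_labels, collapse = "\t")),
    paste0("#state\t", if (is.na(rec$state)) "NA" else rec$state)), con)
  utils::write.table(
    format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EEG recording written by [write_recording()]
#'
#' @param path file path.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L)
    stop("malformed recording file '", path, "': expected 3 header lines ",
         "and at least one data row, got ", length(lines), " line(s)")
  hdr <- function(i, tag) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (parts[[1]] != tag)
      stop("malformed recording file '", path, "' at line ", i,
           ": expected '", tag, "', found '", parts[[1]], "'")
    parts[-1]
  }
  fs <- as.numeric(hdr(1, "#fs"))
  labels <- hdr(2, "#channels")
  state <- hdr(3, "#state")
  state <- if (identical(state, "NA")) NA_character_ else state
  rows <- lapply(seq_along(lines)[-(1:3)], function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]))
    if (anyNA(vals))
      stop("malformed recording file '", path, "' at line ", i,
           ": non-numeric sample value")
    vals
  })
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    stop("malformed recording file '", path, "': rows have unequal lengths")
  eeg_recording(do.call(rbind, rows), fs = fs, channel_labels = labels,
                state = state)
}

#' Clinical covariate records
#'
#' Builds and validates the patient covariate table used for screening and
#' the clinical probability model: age (years), sex (F/M), three binary
#' comorbidities, an eye-movement test score, and the state label.
#'
#' @param df data.frame with columns `age`, `sex`, `hypertension`,
#'   `hyperlipidemia`, `diabetes`, `eye_movement`, `label`.
#' @return the validated data.frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  needed <- c("age", "sex", "hypertension", "hyperlipidemia", "diabetes",
              "eye_movement", "label")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$age < 40 | df$age > 100)) stop("age must lie in [40, 100]")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  for (b in c("hypertension", "hyperlipidemia", "diabetes"))
    if (!all(df[[b]] %in% c(0, 1))) stop(b, " must be binary 0/1")
  if (!all(df$label %in% eeg_states))
    stop("label must be one of: ", paste(eeg_states, collapse = ", "))
  if (!all(is.finite(df$eye_movement))) stop("eye_movement must be finite")
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' @rdname clinical_table
#' @param path CSV file path.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname clinical_table
#' @export
read_clinical_table <- function(path) {
  clinical_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
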