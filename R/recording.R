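# Subject and dyad recordings: validated multichannel time series bound to
# a montage and a sampling rate.

#' Construct a subject recording
#'
#' @param samples numeric matrix, rows = time samples, columns = channels in
#'   montage order.
#' @param montage a [channel_montage].
#' @param sampling_rate sampling rate in Hz (default 7.81).
#' @param chromophore `"HbO2"` or `"HHb"`.
#' @return An object of class `subject_recording`.
#' @export
subject_recording <- function(samples, montage, sampling_rate = 7.81,
                              chromophore = c("HbO2", "HHb")) {
  chromophore <- match.arg(chromophore)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!inherits(montage, "channel_montage"))
    stop("montage must be a channel_montage")
  if (ncol(samples) != length(montage$channels))
    stop("recording has ", ncol(samples), " columns but montage has ",
         length(montage$channels), " channels")
  if (nrow(samples) < 3)
    stop("recording needs at least 3 samples (rank correlation requires ",
         ">= 3 time points), got ", nrow(samples))
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("recording contains missing or non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  colnames(samples) <- montage$channels
  structure(list(samples = samples, montage = montage,
                 sampling_rate = sampling_rate, chromophore = chromophore),
            class = "subject_recording")
}

#' Read a recording CSV
#'
#' Comma-separated, mandatory header row of channel names, one time sample
#' per subsequent row (time increases downward).  Columns are reordered to
#' montage order; the file must contain exactly the montage's channels.
#'
#' @param path CSV file path.
#' @param montage a [channel_montage] naming the expected channels.
#' @param sampling_rate sampling rate in Hz.
#' @param chromophore chromophore label for the stored series.
#' @return A [subject_recording].
#' @export
read_recording <- function(path, montage, sampling_rate = 7.81,
                           chromophore = "HbO2") {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_ch <- setdiff(montage$channels, names(df))
  extra_ch <- setdiff(names(df), montage$channels)
  if (length(missing_ch) || length(extra_ch))
    stop("montage mismatch in ", path,
         if (length(missing_ch)) paste0(": missing channel(s) ",
                                        paste(missing_ch, collapse = ", ")),
         if (length(extra_ch)) paste0("; unknown channel(s) ",
                                      paste(extra_ch, collapse = ", ")))
  df <- df[, montage$channels, drop = FALSE]
  mat <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1,
                                    dimnames = list(NULL, names(df)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("parse error in ", path, ": non-numeric value at row ", bad[1],
         ", channel ", montage$channels[bad[2]])
  }
  subject_recording(mat, montage, sampling_rate, chromophore)
}

#' @rdname read_recording
#' @param recording a [subject_recording] to write.
#' @export
write_recording <- function(recording, path) {
  utils::write.table(recording$samples, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pair two recordings into a validated dyad
#'
#' @param teacher,child [subject_recording]s with equal length, equal
#'   sampling rate and the same chromophore.
#' @param dyad_id label for the dyad.
#' @return An object of class `dyad_recording`.
#' @export
validate_dyad <- function(teacher, child, dyad_id = "dyad") {
  stopifnot(inherits(teacher, "subject_recording"),
            inherits(child, "subject_recording"))
  if (nrow(teacher$samples) != nrow(child$samples))
    stop("length mismatch: teacher has ", nrow(teacher$samples),
         " samples, child has ", nrow(child$samples))
  if (!isTRUE(all.equal(teacher$sampling_rate, child$sampling_rate)))
    stop("sampling rate mismatch: ", teacher$sampling_rate, " vs ",
         child$sampling_rate, " Hz")
  if (teacher$chromophore != child$chromophore)
    stop("chromophore mismatch: ", teacher$chromophore, " vs ",
         child$chromophore)
  structure(list(teacher = teacher, child = child,
                 dyad_id = as.character(dyad_id)),
            class = "dyad_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat("<subject_recording> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " channels @ ", x$sampling_rate, " Hz (",
      x$chromophore, ", role=", x$montage$subject_role, ")\n", sep = "")
  invisible(x)
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat("<dyad_recording> '", x$dyad_id, "': T=", nrow(x$teacher$samples),
      ", ", ncol(x$teacher$samples), "+", ncol(x$child$samples),
      " channels @ ", x$teacher$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}
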