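#' Epoched EEG recordings
#'
#' The package's container for one subject's EEG: a numeric array of
#' epochs x channels x samples (microvolts), the sampling rate, channel
#' labels, and subject metadata. Epochs are treated everywhere as independent
#' realizations of the same stationary process.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param subject_id subject identifier string.
#' @param group `"patient"` or `"control"` (or `NA` when unknown).
#' @param montage optional [new_montage()] object.
#' @param annotations optional character vector, one per epoch (e.g.
#'   eyes-open / eyes-closed block labels).
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels,
                          subject_id = "S01", group = NA_character_,
                          montage = NULL, annotations = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0,
            length(channel_labels) == dim(data)[2])
  if (!is.null(montage) && length(montage$labels) != dim(data)[2]) {
    stop("channel count does not match montage", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, montage = montage,
         annotations = annotations),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_recording> %s [%s]: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Cut a continuous multichannel record into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs; any trailing remainder shorter than
#' one epoch is dropped.
#'
#' @param data numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch length in seconds (default 2).
#' @inheritParams new_recording
#' @return An `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(512 * 7 * 2), ncol = 2)  # 7 s at 512 Hz, 2 channels
#' dim(epoch_data(x, fs = 512)$data)          # 3 epochs x 2 x 1024
#' @export
epoch_data <- function(data, fs, epoch_len_s = 2, channel_labels = NULL,
                       subject_id = "S01", group = NA_character_,
                       montage = NULL) {
  stopifnot(is.matrix(data), epoch_len_s > 0)
  len <- as.integer(round(epoch_len_s * fs))
  if (nrow(data) < len) {
    stop("record shorter than one epoch", call. = FALSE)
  }
  n_ep <- nrow(data) %/% len
  k <- ncol(data)
  arr <- array(NA_real_, c(n_ep, k, len))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- t(data[((e - 1) * len + 1):(e * len), , drop = FALSE])
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data) %||% sprintf("E%03d", seq_len(k))
  }
  new_recording(arr, fs, channel_labels, subject_id, group, montage)
}

#' Concatenate the epochs of a recording back into a continuous matrix
#'
#' Inverse of [epoch_data()] up to the dropped remainder.
#' @param recording an `eeg_recording`.
#' @return numeric matrix, samples x channels.
#' @export
as_continuous <- function(recording) {
  d <- dim(recording$data)
  out <- matrix(NA_real_, d[1] * d[3], d[2])
  for (e in seq_len(d[1])) {
    out[((e - 1) * d[3] + 1):(e * d[3]), ] <- t(recording$data[e, , ])
  }
  colnames(out) <- recording$channel_labels
  out
}

#' @rdname new_recording
#' @param x an `eeg_recording`.
#' @param ... unused.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[1]), each = d[2] * d[3]),
    channel = rep(rep(x$channel_labels, each = d[3]), times = d[1]),
    time_s = rep(seq_len(d[3]) / x$fs, times = d[1] * d[2]),
    value = as.vector(aperm(x$data, c(3, 2, 1))))
}
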