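#' Zero-phase band-limiting and mains-notch filtering
#'
#' Applies, per channel and per epoch, a forward-backward (zero-phase)
#' Butterworth low-pass, high-pass and narrow band-stop (notch) filter.
#' Defaults follow the standard resting-state contract: low-pass 100 Hz,
#' high-pass 0.5 Hz, notch 50 Hz (mains) with a 2 Hz stop band.
#'
#' @param recording an [new_recording()].
#' @param low_pass_hz low-pass cutoff in Hz (`NULL` to skip).
#' @param high_pass_hz high-pass cutoff in Hz (`NULL` to skip).
#' @param notch_hz notch center in Hz (`NULL` to skip).
#' @param notch_width_hz full width of the stop band (default 2).
#' @param order Butterworth order (default 4; the notch uses order 2).
#'
#' @details Epochs of one recording are consecutive segments of the same
#' record, so the filters run over the concatenated record (with odd-symmetric
#' reflection padding of up to 4 s per end to absorb the start-up transient —
#' the 0.5 Hz high-pass settles over seconds, longer than one epoch) and the
#' result is re-epoched. Filtered values near the record ends therefore carry
#' the usual residual edge transient; everything interior is steady-state.
#' @return the filtered recording.
#' @export
apply_filters <- function(recording, low_pass_hz = 100, high_pass_hz = 0.5,
                          notch_hz = 50, notch_width_hz = 2, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  nyq <- fs / 2
  for (co in c(low_pass_hz, high_pass_hz, notch_hz)) {
    if (!is.null(co) && co >= nyq) {
      stop("filter cutoff at or above Nyquist frequency", call. = FALSE)
    }
  }
  if (!is.null(low_pass_hz) && fs <= 2 * low_pass_hz) {
    stop("sampling rate must exceed twice the low-pass cutoff", call. = FALSE)
  }
  filts <- list()
  if (!is.null(high_pass_hz)) {
    filts <- c(filts, list(signal::butter(order, high_pass_hz / nyq, "high")))
  }
  if (!is.null(low_pass_hz)) {
    filts <- c(filts, list(signal::butter(order, low_pass_hz / nyq, "low")))
  }
  if (!is.null(notch_hz)) {
    edges <- c(notch_hz - notch_width_hz / 2, notch_hz + notch_width_hz / 2)
    filts <- c(filts, list(signal::butter(2, edges / nyq, "stop")))
  }
  x <- as_continuous(recording)
  pad <- min(nrow(x) - 1, round(4 * fs))
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    for (f in filts) v <- .filtfilt_pad(f, v, pad)
    x[, ch] <- v
  }
  d <- dim(recording$data)
  for (e in seq_len(d[1])) {
    recording$data[e, , ] <- t(x[((e - 1) * d[3] + 1):(e * d[3]), ,
                                  drop = FALSE])
  }
  recording
}

# Zero-phase filtering with odd-symmetric reflection padding so the
# forward-backward transient decays inside the padding, not the data.
.filtfilt_pad <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(n - 1, pad)
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(pad + 1):(pad + n)]
}

#' Statistical bad-channel detection
#'
#' Flags channels that stand out from the montage on either of two robust
#' criteria aimed at noise contamination:
#' \itemize{
#'   \item log variance of the first-differenced signal. Differencing
#'     emphasizes broadband/high-frequency content (electrode noise, line
#'     interference, muscle) while suppressing physiological band-limited
#'     rhythms by orders of magnitude, so a channel with a strong theta or
#'     alpha rhythm is not mistaken for a noisy one. Flagged two-sided
#'     (noisy or dead channels).
#'   \item mean correlation with the channel's spatial neighbours, flagged
#'     one-sided (only *de*correlated channels — unusually high neighbour
#'     correlation is not a noise signature).
#' }
#' Each criterion is converted to a robust z-score (median / MAD across
#' channels) and compared against `z_thresh`.
#'
#' To stay calibrated on homogeneous recordings (where the across-channel
#' spread is tiny and a bare z threshold would flag clean channels), each
#' criterion also carries a practical-effect floor: a channel must deviate by
#' at least `var_floor_log` in log variance (default `log(2)`: a twofold
#' variance difference) or `cor_floor` in neighbour correlation (default 0.2)
#' in addition to exceeding the z threshold.
#'
#' @param recording an [new_recording()].
#' @param montage a [new_montage()] matching the recording's channels.
#' @param z_thresh robust z threshold (default 3).
#' @param var_floor_log,cor_floor minimal absolute deviations (see Details).
#' @return object of class `channel_quality_report`: tibble with columns
#'   `channel`, `z_log_variance`, `z_neighbor_cor`, `flagged`, plus
#'   attributes `flagged` (labels) and `z_thresh`.
#' @export
detect_bad_channels <- function(recording, montage, z_thresh = 3,
                                var_floor_log = log(2), cor_floor = 0.2) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- dim(recording$data)
  if (d[2] < 4) stop("bad-channel detection needs at least 4 channels",
                     call. = FALSE)
  # concatenate epochs: samples x channels
  x <- as_continuous(recording)
  log_var <- log(apply(diff(x), 2, stats::var))
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  nb_cor <- vapply(seq_len(d[2]), function(i) {
    mean(cm[i, montage$neighbors[[i]]])
  }, numeric(1))
  robust_z <- function(v) {
    s <- stats::mad(v)
    if (s == 0) s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - stats::median(v)) / s
  }
  z_v <- robust_z(log_var)
  z_c <- robust_z(nb_cor)
  dev_v <- abs(log_var - stats::median(log_var))
  dev_c <- stats::median(nb_cor) - nb_cor       # positive = decorrelated
  flagged <- (abs(z_v) > z_thresh & dev_v > var_floor_log) |
    (z_c < -z_thresh & dev_c > cor_floor)
  rep_tbl <- tibble::tibble(channel = recording$channel_labels,
                            z_log_variance = z_v, z_neighbor_cor = z_c,
                            flagged = flagged)
  structure(rep_tbl,
            flagged = recording$channel_labels[flagged],
            z_thresh = z_thresh,
            class = c("channel_quality_report", class(rep_tbl)))
}

#' Replace bad channels by an inverse-distance-weighted neighbour average
#'
#' Each flagged channel is replaced, sample by sample, by the weighted mean of
#' its clean (unflagged) neighbours, with weights proportional to the inverse
#' chord distance to each neighbour. The result is a convex combination, so
#' interpolated values always lie within the neighbours' range.
#'
#' @param recording an [new_recording()].
#' @param report a [detect_bad_channels()] report.
#' @param montage the montage used for detection.
#' @return the recording with flagged channels replaced.
#' @export
interpolate_bad_channels <- function(recording, report, montage) {
  flagged_lab <- attr(report, "flagged")
  if (length(flagged_lab) == 0) return(recording)
  flagged <- match(flagged_lab, recording$channel_labels)
  for (ch in flagged) {
    nb <- montage$neighbors[[ch]]
    clean <- setdiff(nb, flagged)
    if (length(clean) == 0) {
      stop(sprintf("channel %s has no clean neighbour to interpolate from",
                   recording$channel_labels[ch]), call. = FALSE)
    }
    dist <- sqrt(colSums((t(montage$positions[clean, , drop = FALSE]) -
                            montage$positions[ch, ])^2))
    w <- (1 / dist) / sum(1 / dist)
    d <- dim(recording$data)
    for (e in seq_len(d[1])) {
      seg <- matrix(recording$data[e, clean, , drop = FALSE],
                    nrow = length(clean))   # clean-neighbours x samples
      recording$data[e, ch, ] <- as.vector(crossprod(seg, w))
    }
  }
  recording
}

#' Drop epochs with artifact-level amplitudes
#'
#' Removes every epoch whose peak absolute amplitude on any channel exceeds
#' the threshold (an automated surrogate for visual artifact selection).
#'
#' @param recording an [new_recording()].
#' @param abs_amp_uv amplitude threshold in microvolts (default 150).
#' @return the recording restricted to retained epochs, with attribute
#'   `n_rejected`.
#' @export
reject_artifact_epochs <- function(recording, abs_amp_uv = 150) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- dim(recording$data)
  if (d[1] < 1) stop("recording has no epochs", call. = FALSE)
  peak <- apply(abs(recording$data), 1, max)
  keep <- peak <= abs_amp_uv
  if (!any(keep)) stop("no epoch survives the amplitude threshold", call. = FALSE)
  recording$data <- recording$data[keep, , , drop = FALSE]
  if (!is.null(recording$annotations)) {
    recording$annotations <- recording$annotations[keep]
  }
  attr(recording, "n_rejected") <- sum(!keep)
  recording
}

#' Full preprocessing pass
#'
#' Filters, detects and interpolates bad channels, and rejects artifact
#' epochs, in that order. Each step is individually exported; this is the
#' pipeline convenience wrapper.
#'
#' @inheritParams apply_filters
#' @inheritParams detect_bad_channels
#' @inheritParams reject_artifact_epochs
#' @param montage montage used for bad-channel handling; defaults to the
#'   recording's own.
#' @return the cleaned recording.
#' @export
preprocess_recording <- function(recording, montage = recording$montage,
                                 low_pass_hz = 100, high_pass_hz = 0.5,
                                 notch_hz = 50, z_thresh = 3,
                                 abs_amp_uv = 150) {
  rec <- apply_filters(recording, low_pass_hz, high_pass_hz, notch_hz)
  if (!is.null(montage) && dim(rec$data)[2] >= 4) {
    rep <- detect_bad_channels(rec, montage, z_thresh)
    rec <- interpolate_bad_channels(rec, rep, montage)
  }
  reject_artifact_epochs(rec, abs_amp_uv)
}
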