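#' Write an epoched recording as an EDF file
#'
#' Minimal European Data Format writer: one data record per epoch, 16-bit
#' samples scaled over each channel's physical range (microvolts). Lossless
#' up to the 16-bit quantization of that range.
#'
#' @param recording an [new_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  d <- dim(recording$data)
  ns <- d[2]
  nsamp <- d[3]
  n_rec <- d[1]
  dur <- nsamp / recording$fs
  pmin <- apply(recording$data, 2, min)
  pmax <- apply(recording$data, 2, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  pad <- function(x, n) {
    x <- substr(format(x), 1, n)
    sprintf(sprintf("%%-%ds", n), x)
  }
  num <- function(x, n) pad(formatC(x, digits = 6, format = "g"), n)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad(recording$subject_id, 80),
    pad(paste("group:", recording$group), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256 + ns * 256), 8), pad("", 44),
    pad(as.character(n_rec), 8), num(dur, 8), pad(as.character(ns), 4),
    paste(vapply(recording$channel_labels, pad, "", n = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, num, "", n = 8), collapse = ""),
    paste(vapply(pmax, num, "", n = 8), collapse = ""),
    paste(rep(pad("-32768", 8), ns), collapse = ""),
    paste(rep(pad("32767", 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(as.character(nsamp), 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")),
    con, eos = NULL)
  scale <- (pmax - pmin) / 65535
  for (e in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- round((recording$data[e, ch, ] - pmin[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an epoched recording
#'
#' Each EDF data record becomes one epoch. Physical values are reconstructed
#' from the stored digital range. Truncated or malformed files raise an error
#' (with the failing byte offset) rather than returning a partial read.
#'
#' @param path an EDF file written by [write_edf()] or any fixed-rate,
#'   equal-samples-per-signal EDF.
#' @param montage optional montage to attach (channel counts must match).
#' @return an [new_recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (shorter than 256-byte header)",
                                  call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  if (identical(as.integer(first), 255L)) {
    stop("24-bit BDF files are not supported; export as 16-bit EDF",
         call. = FALSE)
  }
  seek(con, 0)
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  subject_id <- trimws(rd(80))
  rec_id <- trimws(rd(80))
  rd(8); rd(8)
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur)) {
    stop("malformed EDF header at byte 236", call. = FALSE)
  }
  if (header_bytes != 256 + ns * 256) {
    stop(sprintf("malformed EDF header: header byte count %d at byte 184",
                 header_bytes), call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  pmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(80 * ns)
  nsamp <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(32 * ns)
  if (length(unique(nsamp)) != 1) {
    stop("signals with unequal sampling rates are not supported", call. = FALSE)
  }
  expect <- header_bytes + 2 * n_rec * sum(nsamp)
  if (sz < expect) {
    stop(sprintf("truncated EDF file: expected %d bytes, found %d", expect, sz),
         call. = FALSE)
  }
  ne <- nsamp[1]
  fs <- ne / dur
  arr <- array(NA_real_, c(n_rec, ns, ne))
  for (e in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = ne, size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < ne) stop("truncated EDF data section", call. = FALSE)
      arr[e, ch, ] <- (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) /
        (dmax[ch] - dmin[ch]) + pmin[ch]
    }
  }
  group <- if (grepl("^group: ", rec_id)) sub("^group: ", "", rec_id)
           else NA_character_
  if (!is.null(montage) && length(montage$labels) != ns) {
    stop("channel count does not match montage", call. = FALSE)
  }
  new_recording(arr, fs, labels, subject_id = subject_id, group = group,
                montage = montage)
}

#' Write a simulated cohort to disk as EDF files plus manifests
#'
#' One EDF file per subject, a tabular cohort manifest (subject id, group,
#' seed, file) and the planted ground-truth edge list as tab-separated text.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$recordings, function(r) {
    f <- file.path(dir, paste0(r$subject_id, ".edf"))
    write_edf(r, f)
    f
  }, "")
  manifest <- dplyr::mutate(cohort$manifest, file = files)
  utils::write.table(manifest, file.path(dir, "cohort_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
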