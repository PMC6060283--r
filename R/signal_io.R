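# Reading, preprocessing and annotating continuous multichannel iEEG.
#
# Time convention: seconds from recording start, 0-based, half-open
# intervals [a, b). Signals are stored channel-major (one row per channel).

#' Construct a multichannel recording
#'
#' A `Recording` bundles a channel-major signal matrix with its sampling rate,
#' channel identifiers and seizure annotations. All downstream stages
#' (filtering, entropy extraction, labelling) operate on this container.
#'
#' @param signal Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Character vector of channel names; defaults to
#'   `"CH1"..."CHn"`.
#' @param annotations Data frame with columns `onset` and `offset`
#'   (seconds, recording-relative, half-open `[onset, offset)`), or `NULL`.
#' @return An object of class `Recording`.
#' @export
recording <- function(signal, fs, channel_ids = NULL, annotations = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    .stopf("'signal' must be a numeric matrix (channels x samples)")
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    .stopf("'signal' must have at least one channel and one sample")
  .check_scalar_num(fs, "fs", lower = .Machine$double.eps)
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(nrow(signal)))
  if (length(channel_ids) != nrow(signal))
    .stopf("length(channel_ids) [%d] != n_channels [%d]",
           length(channel_ids), nrow(signal))
  if (anyDuplicated(channel_ids))
    .stopf("channel ids must be unique")
  rownames(signal) <- channel_ids
  annotations <- .validate_annotations(annotations, ncol(signal) / fs)
  structure(
    list(signal = signal, fs = fs, channel_ids = as.character(channel_ids),
         start_time = 0, annotations = annotations),
    class = "Recording")
}

.validate_annotations <- function(ann, duration_s) {
  if (is.null(ann) || NROW(ann) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  ann <- as.data.frame(ann)
  if (!all(c("onset", "offset") %in% names(ann)))
    .stopf("annotations need 'onset' and 'offset' columns")
  if (any(!is.finite(ann$onset)) || any(!is.finite(ann$offset)))
    .stopf("annotation times must be finite")
  if (any(ann$onset < 0) || any(ann$offset > duration_s + 1e-9))
    .stopf("annotation outside record duration [0, %.3f] s", duration_s)
  if (any(ann$onset >= ann$offset))
    .stopf("each annotation must satisfy onset < offset")
  ann <- ann[order(ann$onset), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, rec_duration(x)))
  cat("  channels:", paste(utils::head(x$channel_ids, 8), collapse = ", "),
      if (length(x$channel_ids) > 8) "..." else "", "\n")
  cat(sprintf("  seizure annotations: %d\n", nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `Recording`.
#' @return Duration `n_samples / fs` in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Preprocessing configuration
#'
#' @param notch_freq Power-line frequency to reject, Hz (default 50).
#' @param notch_bandwidth Full stop-band width of the band-reject filter, Hz.
#' @param target_fs Sampling rate the recording is resampled to, Hz.
#' @param selected_channels Channel ids to keep (typically 6), or `NULL` for
#'   all.
#' @return An object of class `PreprocessConfig`.
#' @export
preprocess_config <- function(notch_freq = 50, notch_bandwidth = 1,
                              target_fs = 256, selected_channels = NULL) {
  .check_scalar_num(notch_freq, "notch_freq", lower = 0)
  .check_scalar_num(notch_bandwidth, "notch_bandwidth",
                    lower = .Machine$double.eps)
  .check_scalar_num(target_fs, "target_fs", lower = .Machine$double.eps)
  if (notch_freq >= target_fs / 2)
    .stopf("notch_freq (%g) must be below the target Nyquist (%g)",
           notch_freq, target_fs / 2)
  structure(list(notch_freq = notch_freq, notch_bandwidth = notch_bandwidth,
                 target_fs = target_fs,
                 selected_channels = selected_channels),
            class = "PreprocessConfig")
}

# readers -------------------------------------------------------------------

#' Read a recording from disk
#'
#' Two dialects are supported. `format = "matrix"`: a delimited text file
#' with one row per channel; sampling rate and channel ids come from a
#' sidecar JSON header `<path>.json` (fields `fs`, `channel_ids`) or from
#' `fs_hint`. `format = "edf"`: a standard EDF/EDF+ file (16-bit samples;
#' all signals must share one sampling rate).
#'
#' Annotations may be supplied as a sidecar text file with one
#' `onset offset` pair (seconds, whitespace- or comma-separated) per line.
#'
#' @param path Path to the signal file.
#' @param format `"matrix"` or `"edf"`.
#' @param fs_hint Sampling rate in Hz; required for matrix files without a
#'   JSON header, ignored for EDF.
#' @param annotation_path Optional path to a seizure annotation file.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("matrix", "edf"), fs_hint = NULL,
                           annotation_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("cannot read '%s': no such file", path)
  rec <- switch(format,
    matrix = .read_matrix_recording(path, fs_hint),
    edf    = read_edf(path))
  if (!is.null(annotation_path)) {
    ann <- read_annotations(annotation_path)
    rec$annotations <- .validate_annotations(ann, rec_duration(rec))
  }
  rec
}

.read_matrix_recording <- function(path, fs_hint) {
  header_path <- paste0(path, ".json")
  fs <- fs_hint
  if (!is.null(fs) && !is.finite(fs)) fs <- NULL   # NA hint = absent
  channel_ids <- NULL
  if (file.exists(header_path)) {
    hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
    if (is.null(fs)) fs <- hdr$fs
    channel_ids <- hdr$channel_ids
  }
  if (is.null(fs))
    .stopf("sampling rate unknown: give fs_hint or a '%s' header", header_path)
  # channels are rows; scan() instead of read.table() because recordings
  # easily span 10^5+ columns
  n_per_row <- length(scan(path, nlines = 1, quiet = TRUE))
  vals <- scan(path, quiet = TRUE)
  n_ch <- length(vals) / n_per_row
  if (n_ch != round(n_ch)) .stopf("'%s' is not rectangular", path)
  mat <- matrix(vals, nrow = as.integer(n_ch), byrow = TRUE)
  recording(mat, fs = fs, channel_ids = channel_ids)
}

#' Write a recording in the plain matrix dialect
#'
#' Emits the delimited signal matrix plus the sidecar JSON header read back
#' by [read_recording()], and optionally the annotation sidecar.
#'
#' @param rec A `Recording`.
#' @param path Output path for the matrix file (header goes to
#'   `<path>.json`, annotations to `<path>.ann` when present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  write.table(rec$signal, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_ids = rec$channel_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (nrow(rec$annotations) > 0L)
    write.table(rec$annotations, paste0(path, ".ann"),
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a seizure annotation sidecar file
#'
#' One seizure per line: onset and offset in seconds from recording start,
#' separated by whitespace or a comma. Lines starting with `#` are skipped.
#'
#' @param path Annotation file path.
#' @return Data frame with `onset` and `offset` columns, sorted by onset.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) .stopf("cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  fields <- lapply(strsplit(lines, "[,[:space:]]+"), as.numeric)
  if (any(vapply(fields, length, 1L) != 2L) || anyNA(unlist(fields)))
    .stopf("annotation lines must hold exactly two numbers (onset offset)")
  m <- do.call(rbind, fields)
  data.frame(onset = m[, 1], offset = m[, 2])
}

# EDF -----------------------------------------------------------------------
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by
# little-endian 16-bit samples, record-major. Physical values are linearly
# rescaled from the digital range declared per signal.

.edf_field <- function(con, nbytes) trimws(readChar(con, nbytes, useBytes = TRUE))

#' Read an EDF/EDF+ file
#'
#' Minimal reader for continuous EDF recordings in which every ordinary
#' signal shares one sampling rate (EDF+ annotation signals are dropped).
#'
#' @param path EDF file path.
#' @return A [recording()] with physical (scaled) sample values.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_field(con, 8)
  if (!identical(version, "0")) .stopf("'%s' is not an EDF file", path)
  .edf_field(con, 80); .edf_field(con, 80)          # patient, recording id
  .edf_field(con, 8); .edf_field(con, 8)            # start date, time
  .edf_field(con, 8)                                # header bytes
  .edf_field(con, 44)                               # reserved
  n_records <- as.integer(.edf_field(con, 8))
  record_dur <- as.numeric(.edf_field(con, 8))
  ns <- as.integer(.edf_field(con, 4))
  if (is.na(ns) || ns < 1L) .stopf("EDF header: bad signal count")
  labels    <- vapply(seq_len(ns), function(i) .edf_field(con, 16), "")
  for (i in seq_len(ns)) .edf_field(con, 80)        # transducer
  for (i in seq_len(ns)) .edf_field(con, 8)         # physical dimension
  phys_min  <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8)), 1)
  phys_max  <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8)), 1)
  dig_min   <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8)), 1)
  dig_max   <- vapply(seq_len(ns), function(i) as.numeric(.edf_field(con, 8)), 1)
  for (i in seq_len(ns)) .edf_field(con, 80)        # prefiltering
  spr       <- vapply(seq_len(ns), function(i) as.integer(.edf_field(con, 8)), 1L)
  for (i in seq_len(ns)) .edf_field(con, 32)        # reserved

  keep <- labels != "EDF Annotations"
  if (!any(keep)) .stopf("EDF file contains no ordinary signals")
  if (length(unique(spr[keep])) != 1L || record_dur <= 0)
    .stopf("EDF signals with mixed sampling rates are not supported")
  fs <- spr[keep][1] / record_dur

  sig <- matrix(NA_real_, sum(keep), n_records * spr[keep][1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  row_of <- cumsum(keep)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[s]) .stopf("EDF file truncated in record %d", r)
      if (keep[s]) {
        cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        sig[row_of[s], cols] <- phys_min[s] + gain[s] * (raw - dig_min[s])
      }
    }
  }
  recording(sig, fs = fs, channel_ids = labels[keep])
}

#' Write a recording as EDF
#'
#' Counterpart to [read_edf()], mainly used to materialise synthetic
#' recordings in a standard interchange format. Samples are quantised to the
#' 16-bit digital range spanned by each channel.
#'
#' @param rec A `Recording`; `fs * record_duration` must be an integer.
#' @param path Output path.
#' @param record_duration EDF data-record length in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  spr <- rec$fs * record_duration
  if (abs(spr - round(spr)) > 1e-9)
    .stopf("fs * record_duration must be an integer number of samples")
  spr <- as.integer(round(spr))
  n_records <- floor(ncol(rec$signal) / spr)
  if (n_records < 1L) .stopf("recording shorter than one EDF data record")
  ns <- nrow(rec$signal)
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

  phys_min <- apply(rec$signal, 1, min)
  phys_max <- apply(rec$signal, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- rep(-32768L, ns); dig_max <- rep(32767L, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(pad("0", 8), pad("X", 80), pad("X", 80),
           pad("01.01.00", 8), pad("00.00.00", 8),
           pad(256L * (1L + ns), 8), pad("", 44),
           pad(n_records, 8), pad(format(record_duration), 8), pad(ns, 4),
           pad(rec$channel_ids, 16), rep(pad("", 80), ns),
           rep(pad("uV", 8), ns),
           pad(formatC(phys_min, format = "g", digits = 6), 8),
           pad(formatC(phys_max, format = "g", digits = 6), 8),
           pad(dig_min, 8), pad(dig_max, 8),
           rep(pad("", 80), ns), pad(rep(spr, ns), 8), rep(pad("", 32), ns))
  writeChar(paste(hdr, collapse = ""), con, eos = NULL, useBytes = TRUE)

  # re-read the header's truncated physical range so scaling is exactly
  # invertible on read
  pmin_w <- as.numeric(formatC(phys_min, format = "g", digits = 6))
  pmax_w <- as.numeric(formatC(phys_max, format = "g", digits = 6))
  gain <- (pmax_w - pmin_w) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((rec$signal[s, cols] - pmin_w[s]) / gain[s]) + dig_min[s]
      dig <- pmin(pmax(dig, dig_min[s]), dig_max[s])
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# preprocessing --------------------------------------------------------------

#' Remove power-line interference with a zero-phase notch filter
#'
#' Applies a second-order Butterworth band-reject filter forwards and
#' backwards ([signal::filtfilt()]) so the filter adds no phase delay that
#' would shift onset-relative timing.
#'
#' @param rec A `Recording`.
#' @param cfg A [preprocess_config()]; `notch_freq` must lie below the
#'   recording's Nyquist frequency.
#' @return A new `Recording` of identical shape.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  f0 <- cfg$notch_freq
  bw <- cfg$notch_bandwidth
  if (f0 >= rec$fs / 2)
    .stopf("notch_freq (%g Hz) is not below Nyquist (%g Hz)", f0, rec$fs / 2)
  band <- c(max(f0 - bw / 2, 1e-6), min(f0 + bw / 2, rec$fs / 2 * 0.999))
  filt <- signal::butter(2, band / (rec$fs / 2), type = "stop")
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(x)
    signal::filtfilt(filt, x)))
  rownames(out$signal) <- rec$channel_ids
  out
}

#' Resample a recording to a new rate
#'
#' Polyphase rational resampling via [signal::resample()]; downsampling is
#' anti-alias filtered. The output length is `floor(n * target_fs / fs)` so
#' duration is preserved within one output sample period.
#'
#' @param rec A `Recording`.
#' @param target_fs Desired sampling rate, Hz.
#' @return A new `Recording` at `target_fs` (annotations carried over
#'   unchanged; they are expressed in seconds).
#' @export
resample_to <- function(rec, target_fs) {
  .check_scalar_num(target_fs, "target_fs", lower = .Machine$double.eps)
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  frac <- .rational_approx(target_fs / rec$fs)
  n_out <- floor(ncol(rec$signal) * target_fs / rec$fs)
  out_sig <- t(apply(rec$signal, 1, function(x) {
    y <- signal::resample(x, frac[1], frac[2])
    length(y) <- n_out              # truncate/pad the polyphase tail
    y[is.na(y)] <- 0
    y
  }))
  out <- rec
  out$signal <- out_sig
  rownames(out$signal) <- rec$channel_ids
  out$fs <- target_fs
  out$annotations <- .validate_annotations(out$annotations, n_out / target_fs)
  out
}

.rational_approx <- function(x, max_den = 1024L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(as.integer(p), q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Subset and reorder channels
#'
#' @param rec A `Recording`.
#' @param ids Channel ids to keep, in the desired order.
#' @return A new `Recording` restricted to `ids`; annotations unchanged.
#' @export
select_channels <- function(rec, ids) {
  missing_ids <- setdiff(ids, rec$channel_ids)
  if (length(missing_ids) > 0L)
    .stopf("unknown channel id(s): %s", paste(missing_ids, collapse = ", "))
  out <- rec
  out$signal <- rec$signal[match(ids, rec$channel_ids), , drop = FALSE]
  out$channel_ids <- as.character(ids)
  rownames(out$signal) <- out$channel_ids
  out
}

#' Run the standard preprocessing chain
#'
#' Notch filtering, resampling to the target rate and channel selection, in
#' that order.
#'
#' @param rec A `Recording`.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `Recording`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  out <- notch_filter(rec, cfg)
  out <- resample_to(out, cfg$target_fs)
  if (!is.null(cfg$selected_channels))
    out <- select_channels(out, cfg$selected_channels)
  out
}
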