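#' Construct an EEG recording object
#'
#' Container for a multichannel sampled EEG signal: a channels-by-samples
#' matrix in microvolts, the sampling rate, and 10-20 channel labels.
#'
#' @param samples Numeric matrix, `n_channels` rows by `n_samples` columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel labels, one per row.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_names = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) stop("all sample values must be finite")
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0)) stop("fs must be a positive scalar")
  if (ncol(samples) < 1) stop("recording must contain at least one sample")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop("channel_names length must equal the number of channels")
  structure(
    list(samples = samples, fs = fs, channel_names = as.character(channel_names)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' The eight segment classes
#'
#' Baseline plus the seven ocular/facial-muscle artifact classes the
#' framework discriminates.
#' @return Character vector of the eight class labels.
#' @export
artifact_classes <- function() {
  c("baseline", "blink", "eye_up", "eye_left", "eyebrow", "head",
    "jaw_clinch", "jaw_move")
}

#' Construct a fixed-length EEG segment
#'
#' @param samples Numeric vector of samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds; `length(samples)` must equal
#'   `round(window_s * fs)`.
#' @param label Optional class label, one of [artifact_classes()].
#' @param source_channel Channel the segment was cut from.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, window_s = length(samples) / fs,
                        label = NULL, source_channel = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) != round(window_s * fs))
    stop("segment length must equal round(window_s * fs)")
  if (!is.null(label)) label <- match.arg(label, artifact_classes())
  structure(
    list(samples = samples, fs = fs, window_s = window_s, label = label,
         source_channel = source_channel),
    class = "eeg_segment"
  )
}

#' Read an EEG recording from disk
#'
#' Reads either a delimited-text matrix (`format = "csv"`: one row per
#' channel, comma-separated; an optional non-numeric first field per row is
#' taken as the channel name) or a European Data Format file
#' (`format = "edf"`).
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; default guesses from the extension.
#' @param fs Sampling rate in Hz for CSV input (EDF carries its own).
#' @param channel Optional channel name or index; its presence is validated
#'   here, selection itself happens in [make_segments()].
#' @return An [eeg_recording()].
#' @export
read_signal <- function(path, format = c("auto", "csv", "edf"), fs = 256,
                        channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else read_csv_matrix(path, fs)
  if (!is.null(channel)) resolve_channel(rec, channel)  # errors if absent
  rec
}

read_csv_matrix <- function(path, fs) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty CSV file: ", path)
  rows <- strsplit(lines, ",")
  first <- trimws(vapply(rows, `[`, "", 1))
  named <- all(is.na(suppressWarnings(as.numeric(first))))
  names_out <- NULL
  if (named) {
    names_out <- first
    rows <- lapply(rows, `[`, -1)
  }
  n <- unique(lengths(rows))
  if (length(n) != 1) stop("inconsistent row lengths in CSV: ", path)
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(trimws(r)), numeric(n[1])))
  if (anyNA(vals)) stop("non-numeric cells in CSV: ", path)
  samples <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = 1)
  eeg_recording(samples, fs = fs, channel_names = names_out)
}

resolve_channel <- function(rec, channel) {
  if (is.numeric(channel)) {
    if (channel < 1 || channel > nrow(rec$samples))
      stop("channel index out of range: ", channel)
    return(as.integer(channel))
  }
  idx <- match(channel, rec$channel_names)
  if (is.na(idx))
    stop("channel not found: '", channel, "' (have: ",
         paste(rec$channel_names, collapse = ", "), ")")
  idx
}

#' Zero-phase high-pass filter an EEG recording
#'
#' Removes DC offset and slow drifts with a 4th-order Butterworth high-pass
#' ([signal::butter()]) applied forward-backward with matched initial
#' conditions and odd-extension padding, so the waveform morphology of
#' transients is preserved without phase delay and start-up transients stay
#' off the data.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz Cut-off frequency in Hz (default 0.5); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
highpass_filter <- function(rec, cutoff_hz = 0.5, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(cutoff_hz > 0 && cutoff_hz < rec$fs / 2))
    stop("cutoff must lie in (0, fs/2)")
  bt <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  # pad with several filter time constants (1 / cutoff) so both passes'
  # transients decay inside the padding
  pad <- round(3 * rec$fs / cutoff_hz)
  filtered <- t(apply(rec$samples, 1,
                      function(x) filtfilt_zi(bt$b, bt$a, x, pad)))
  eeg_recording(filtered, rec$fs, rec$channel_names)
}

#' Cut a channel into fixed-length non-overlapping segments
#'
#' Applies a rectangular window of `window_s` seconds with no overlap;
#' trailing samples that do not fill a whole window are discarded.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel name or index (default the first channel).
#' @param window_s Window length in seconds (default 1).
#' @return A list of [eeg_segment()] objects in temporal order.
#' @export
make_segments <- function(rec, channel = 1, window_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- resolve_channel(rec, channel)
  len <- round(window_s * rec$fs)
  if (len < 8) stop("window must span at least 8 samples")
  x <- rec$samples[idx, ]
  n_seg <- floor(length(x) / len)
  if (n_seg == 0) {
    warning("window longer than recording; returning no segments")
    return(list())
  }
  lapply(seq_len(n_seg), function(j) {
    eeg_segment(x[((j - 1) * len + 1):(j * len)], fs = rec$fs,
                window_s = window_s,
                source_channel = rec$channel_names[idx])
  })
}

# Direct-form-II-transposed IIR filter with explicit initial state.
df2t_filter <- function(b, a, x, zi) {
  n <- length(x)
  m <- length(b) - 1
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1) for (j in seq_len(m - 1)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[m] <- b[m + 1] * xi - a[m + 1] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit-step input (matched initial
# conditions remove the start-up transient of each pass).
filter_zi <- function(b, a) {
  m <- length(a) - 1
  A <- matrix(0, m, m)
  A[1, ] <- -a[2:(m + 1)]
  if (m > 1) A[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[2:(m + 1)] - a[2:(m + 1)] * b[1]
  solve(diag(m) - t(A), B)
}

# Zero-phase forward-backward filtering with odd-extension padding and
# matched initial conditions, so edge transients stay off the data.
filtfilt_zi <- function(b, a, x, pad = 3 * length(a)) {
  n <- length(x)
  zi <- filter_zi(b, a)
  pad <- min(n - 1, pad)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- df2t_filter(b, a, xe, zi * xe[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * rev(y)[1]))
  y[(pad + 1):(pad + n)]
}
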