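# Minimal European Data Format (EDF) I/O.
#
# EDF is a fixed-layout format: a 256-byte ASCII header, 256 ASCII bytes of
# per-signal metadata fields, then data records of little-endian int16
# samples, linearly scaled between digital and physical ranges.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a European Data Format (EDF) file
#'
#' Parses the EDF header and all data records, converting digital values to
#' physical units via the per-signal linear calibration. All signals must
#' share one sampling rate.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_recording()] in the file's physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                       # version
  read_ascii(con, 80); read_ascii(con, 80) # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)   # start date / time
  read_ascii(con, 8)                       # header byte count
  read_ascii(con, 44)                      # reserved
  n_records <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("invalid EDF header: ", path)
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  field(80); field(8)                      # transducer, physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                                # prefiltering
  spr <- as.integer(field(8))              # samples per record
  field(32)                                # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  if (length(unique(spr)) != 1)
    stop("signals with differing sampling rates are not supported")
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  eeg_recording(data, fs = spr[1] / rec_dur, channel_names = labels)
}

pad_ascii <- function(x, w) {
  x <- substr(as.character(x), 1, w)
  formatC(x, width = -w, flag = " ")
}

#' Write an EEG recording to a European Data Format (EDF) file
#'
#' Writes all channels as one EDF data record whose duration is the full
#' recording length, with int16 quantization over the per-channel physical
#' range. Intended for exchanging synthetic or preprocessed recordings.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  phys_min <- apply(rec$samples, 1, min)
  phys_max <- apply(rec$samples, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(pad_ascii(x, w)), con)
  put("0", 8)
  put("synthetic", 80); put("eegmra export", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(256 + 256 * ns, 8)
  put("", 44)
  put(1, 8)                                 # one data record
  put(format(n / rec$fs, digits = 10), 8)   # record duration (s)
  put(ns, 4)
  for (i in seq_len(ns)) put(rec$channel_names[i], 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(format(phys_min[i], digits = 7), 8)
  for (i in seq_len(ns)) put(format(phys_max[i], digits = 7), 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(n, 8)
  for (i in seq_len(ns)) put("", 32)
  for (i in seq_len(ns)) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max - dig_min)
    dig <- round((rec$samples[i, ] - phys_min[i]) / gain + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
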