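# Minimal reader (and unexported writer, used for fixtures) for GDF 2.x, the
# distribution format of BCI Competition IV dataset 2a. Only the fields this
# package needs are interpreted: channel labels, sampling rate, per-channel
# scaling, the signal itself and the event table. All integers little-endian.

GDF_TYPES <- list(`1` = list(what = "integer", size = 1, signed = TRUE),
                  `2` = list(what = "integer", size = 1, signed = FALSE),
                  `3` = list(what = "integer", size = 2, signed = TRUE),
                  `4` = list(what = "integer", size = 2, signed = FALSE),
                  `5` = list(what = "integer", size = 4, signed = TRUE),
                  `16` = list(what = "double", size = 4, signed = TRUE),
                  `17` = list(what = "double", size = 8, signed = TRUE))

read_str <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("truncated GDF header at byte ", seek(con))
  raw <- raw[raw != as.raw(0)]
  trimws(rawToChar(raw))
}

read_u16 <- function(con, n = 1) readBin(con, "integer", n, size = 2,
                                         signed = FALSE, endian = "little")
read_i32 <- function(con, n = 1) readBin(con, "integer", n, size = 4,
                                         endian = "little")
read_u32 <- function(con, n = 1) {
  v <- readBin(con, "integer", n, size = 4, endian = "little")
  ifelse(v < 0, v + 2^32, as.numeric(v))
}
read_f32 <- function(con, n = 1) readBin(con, "double", n, size = 4,
                                         endian = "little")
read_f64 <- function(con, n = 1) readBin(con, "double", n, size = 8,
                                         endian = "little")
read_i64 <- function(con, n = 1) {
  lo <- read_u32(con, n * 2)
  lo[seq(1, 2 * n, 2)] + lo[seq(2, 2 * n, 2)] * 2^32
}

#' Read a GDF 2.x file
#'
#' Parses the fixed header, per-channel headers, all data records and the
#' event table of a GDF 2.x recording (as used by BCI Competition IV-2a).
#' Digital values are rescaled to physical units with the per-channel
#' digital/physical min/max calibration. Event onsets are converted from the
#' format's 1-based sample positions to 0-based.
#'
#' @param path path to a `.gdf` file.
#' @return an [raw_recording()] object.
#' @export
read_gdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_str(con, 8)
  if (!grepl("^GDF", version))
    stop("not a GDF file (magic '", version, "' at byte 0): ", path)
  vnum <- suppressWarnings(as.numeric(sub("^GDF ?", "", version)))
  if (is.na(vnum) || vnum < 1.9)
    stop("unsupported GDF version '", version, "' (only GDF 2.x supported)")

  pid <- read_str(con, 66)
  seek(con, 168)                                # start-of-recording datetime
  invisible(readBin(con, "raw", 16))            # meas date + birthday
  header_nbytes <- read_u16(con) * 256
  seek(con, 236)
  n_records <- read_i64(con)
  rec_dur <- read_u32(con, 2)                   # duration num/denom, seconds
  nchan <- read_u16(con)
  seek(con, 256)

  labels <- vapply(seq_len(nchan), function(i) read_str(con, 16), "")
  seek(con, 256 + nchan * (16 + 80 + 6))        # skip transducer + physdim
  invisible(read_u16(con, nchan))               # physical dimension codes
  physmin <- read_f64(con, nchan)
  physmax <- read_f64(con, nchan)
  digmin <- read_f64(con, nchan)
  digmax <- read_f64(con, nchan)
  seek(con, nchan * 68, origin = "current")     # obsolete prefilter text
  invisible(read_f32(con, 3 * nchan))           # lowpass/highpass/notch
  spr <- read_i32(con, nchan)
  dtype <- read_i32(con, nchan)
  seek(con, header_nbytes)

  if (any(spr != spr[1]))
    stop("channels with differing samples-per-record are not supported")
  fs <- spr[1] * rec_dur[2] / rec_dur[1]

  n_samples <- n_records * spr[1]
  signal <- matrix(0, nchan, n_samples)
  bytes_per_rec <- sum(vapply(dtype, function(t) {
    tt <- GDF_TYPES[[as.character(t)]]
    if (is.null(tt)) stop("unsupported GDF data type code ", t)
    tt$size
  }, 0) * spr)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(nchan)) {
      tt <- GDF_TYPES[[as.character(dtype[ch])]]
      v <- readBin(con, tt$what, n = spr[ch], size = tt$size,
                   signed = tt$signed, endian = "little")
      if (length(v) < spr[ch])
        stop("truncated GDF data in record ", r, " (byte ", seek(con), ")")
      cal <- (physmax[ch] - physmin[ch]) / (digmax[ch] - digmin[ch])
      if (!is.finite(cal)) cal <- 1
      if (abs(cal - 1) > 1e-12 || abs(physmin[ch] - digmin[ch]) > 1e-12)
        v <- (v - digmin[ch]) * cal + physmin[ch]
      signal[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- v
    }
  }

  events <- data.frame(onset = integer(), code = integer())
  etmode_raw <- readBin(con, "raw", 1)
  if (length(etmode_raw) == 1) {
    etmode <- as.integer(etmode_raw)
    if (etmode %in% c(1L, 3L)) {
      ne <- as.integer(readBin(con, "raw", 3))
      nev <- ne[1] + ne[2] * 256 + ne[3] * 65536
      invisible(read_f32(con))                  # event table sampling rate
      pos <- read_u32(con, nev) - 1             # 1-based -> 0-based
      typ <- read_u16(con, nev)
      events <- data.frame(onset = as.integer(pos), code = as.integer(typ))
    }
  }

  raw_recording(signal, labels, fs, events, subject_id = pid)
}

# Write a GDF 2.20 file. Internal: used to build round-trip fixtures in the
# tests; write_raw() is the supported output path for users.
write_gdf <- function(rec, path) {
  validate_raw(rec)
  nchan <- nrow(rec$signal)
  n <- ncol(rec$signal)
  con <- file(path, "wb")
  on.exit(close(con))
  put_str <- function(s, width) {
    raw <- charToRaw(s)
    if (length(raw) > width) raw <- raw[1:width]
    writeBin(c(raw, rep(as.raw(0), width - length(raw))), con)
  }
  put_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                  endian = "little")
  put_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                  endian = "little")
  put_f32 <- function(v) writeBin(as.numeric(v), con, size = 4,
                                  endian = "little")
  put_f64 <- function(v) writeBin(as.numeric(v), con, size = 8,
                                  endian = "little")
  put_i64 <- function(v) { put_u32(v %% 2^32); put_u32(v %/% 2^32) }

  # fixed header (256 bytes); one data record holding the whole signal
  put_str("GDF 2.20", 8)
  put_str(paste0(rec$subject_id, " X"), 66)
  writeBin(rep(as.raw(0), 10 + 4), con)         # reserved + lifestyle bytes
  put_str("clrnet", 64)                         # recording id
  writeBin(rep(as.raw(0), 4 + 12), con)         # location
  put_i64(0); put_i64(0)                        # meas date, birthday
  put_u16((256 + 256 * nchan) / 256)            # header length / 256
  writeBin(rep(as.raw(0), 6 + 8 + 6 + 6 + 12 + 12), con)
  put_i64(1)                                    # number of data records
  put_u32(n); put_u32(rec$fs)                   # record duration n/fs seconds
  put_u16(nchan); put_u16(0)

  # per-channel headers, field-blocked
  for (ch in seq_len(nchan)) put_str(rec$channel_names[ch], 16)
  writeBin(rep(as.raw(0), 80 * nchan), con)     # transducer (reserved)
  writeBin(rep(as.raw(0), 6 * nchan), con)      # obsolete phys dim
  for (ch in seq_len(nchan)) put_u16(4275)      # dimension code: microvolt
  for (ch in seq_len(nchan)) put_f64(-1)        # physmin
  for (ch in seq_len(nchan)) put_f64(1)         # physmax
  for (ch in seq_len(nchan)) put_f64(-1)        # digmin (gain 1, offset 0)
  for (ch in seq_len(nchan)) put_f64(1)         # digmax
  writeBin(rep(as.raw(0), 68 * nchan), con)     # obsolete prefilter
  for (ch in seq_len(nchan)) put_f32(0)         # lowpass
  for (ch in seq_len(nchan)) put_f32(0)         # highpass
  for (ch in seq_len(nchan)) put_f32(0)         # notch
  for (ch in seq_len(nchan)) put_u32(n)         # samples per record
  for (ch in seq_len(nchan)) put_u32(17)        # data type: float64
  writeBin(rep(as.raw(0), 12 * nchan), con)     # sensor xyz
  writeBin(rep(as.raw(0), 20 * nchan), con)     # impedance block (>= 2.19)

  for (ch in seq_len(nchan)) put_f64(rec$signal[ch, ])

  # event table, mode 1
  writeBin(as.raw(1), con)
  nev <- nrow(rec$events)
  writeBin(as.raw(c(nev %% 256, (nev %/% 256) %% 256, nev %/% 65536)), con)
  put_f32(rec$fs)
  for (i in seq_len(nev)) put_u32(rec$events$onset[i] + 1)
  for (i in seq_len(nev)) put_u16(rec$events$code[i])
  invisible(path)
}
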