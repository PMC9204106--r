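# Minimal EDF/EDF+ container support for continuous multichannel recordings.
# EDF stores 16-bit integers with per-channel physical/digital scaling, in
# fixed-duration data records; all channels must share one sampling rate here.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  for (d in 7:0) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop("cannot represent ", x, " in an EDF numeric field of width ", width)
}

#' Write an EEG stream to an EDF(+) file
#'
#' Data are quantized to 16 bits using per-channel physical minima/maxima.
#' Records are 1 s long (or `1/fs` multiples for non-integer rates); the last
#' record is zero-padded, so files hold a whole number of records.
#'
#' @param x a [sensor_stream()] (any kind; typically EEG).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(x, path) {
  stopifnot(inherits(x, "SensorStream"))
  nch <- nrow(x$data)
  rec_dur <- 1
  spr <- x$fs * rec_dur
  if (spr != round(spr)) { rec_dur <- 10; spr <- x$fs * rec_dur }
  if (spr != round(spr)) stop("sampling rate not representable in EDF records")
  spr <- as.integer(round(spr))
  n <- ncol(x$data)
  ndr <- as.integer(ceiling(n / spr))
  # use the header-representable (rounded) physical range for digitization so
  # writer and reader apply the identical scaling
  as_field <- function(v) as.numeric(vapply(v, edf_num, "", width = 8))
  pmin_ <- as_field(apply(x$data, 1, min) - 1e-6 * abs(apply(x$data, 1, min)) - 1e-12)
  pmax_ <- as_field(apply(x$data, 1, max) + 1e-6 * abs(apply(x$data, 1, max)) + 1e-12)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256 * (nch + 1), 8), edf_pad("EDF+C", 44),
    edf_num(ndr, 8), edf_num(rec_dur, 8), edf_num(nch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(x$labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), nch),
    rep(edf_pad(x$units, 8), nch),
    vapply(pmin_, edf_num, "", width = 8),
    vapply(pmax_, edf_num, "", width = 8),
    rep(edf_num(dmin, 8), nch),
    rep(edf_num(dmax, 8), nch),
    rep(edf_pad("", 80), nch),
    rep(edf_num(spr, 8), nch),
    rep(edf_pad("", 32), nch)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  padded <- matrix(0, nch, ndr * spr)
  padded[, seq_len(n)] <- x$data
  for (r in seq_len(ndr)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nch)) {
      dig <- round((padded[ch, idx] - pmin_[ch]) / scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

edf_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

edf_numfield <- function(raw, off, len, name) {
  v <- suppressWarnings(as.numeric(edf_field(raw, off, len)))
  if (is.na(v)) stop(sprintf("EDF format error: header field '%s' is not numeric", name))
  v
}

#' Read an EDF(+) file into a SensorStream
#'
#' @param path path to an EDF or EDF+ file with a common sampling rate across
#'   channels.
#' @param kind stream kind to assign (default `"eeg"`).
#' @return a [sensor_stream()].
#' @export
read_eeg <- function(path, kind = "eeg") {
  if (!file.exists(path)) stop("EDF file does not exist: ", path)
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256) stop("EDF format error: header field 'version' truncated")
  nch <- as.integer(edf_numfield(raw, 252, 4, "number of signals"))
  if (nch < 1) stop("EDF format error: header field 'number of signals' invalid")
  if (length(raw) < 256 * (nch + 1))
    stop("EDF format error: header field 'header bytes' exceeds file size")
  ndr <- as.integer(edf_numfield(raw, 236, 8, "number of data records"))
  rec_dur <- edf_numfield(raw, 244, 8, "record duration")
  if (rec_dur <= 0) stop("EDF format error: header field 'record duration' nonpositive")

  off <- 256
  getf <- function(len) {
    out <- vapply(seq_len(nch) - 1, function(i) edf_field(raw, off + i * len, len), "")
    off <<- off + nch * len
    out
  }
  labels <- getf(16)
  getf(80)                       # transducer
  units <- getf(8)
  pmin_ <- as.numeric(getf(8))
  pmax_ <- as.numeric(getf(8))
  dmin <- as.numeric(getf(8))
  dmax <- as.numeric(getf(8))
  if (anyNA(pmin_) || anyNA(pmax_))
    stop("EDF format error: header field 'physical minimum/maximum' is not numeric")
  if (anyNA(dmin) || anyNA(dmax) || any(dmax <= dmin))
    stop("EDF format error: header field 'digital minimum/maximum' invalid")
  getf(80)                       # prefiltering
  spr <- as.integer(getf(8))
  if (anyNA(spr)) stop("EDF format error: header field 'samples per record' is not numeric")
  getf(32)                       # reserved
  if (length(unique(spr)) != 1)
    stop("EDF format error: header field 'samples per record' differs across channels; a common rate is required")
  if (anyDuplicated(labels))
    stop("EDF format error: header field 'label' contains duplicate channel labels")
  spr <- spr[1]
  fs <- spr / rec_dur

  hdr_bytes <- 256 * (nch + 1)
  nvals <- ndr * nch * spr
  vals <- readBin(raw[(hdr_bytes + 1):length(raw)], "integer", n = nvals,
                  size = 2, endian = "little")
  if (length(vals) < nvals)
    stop("EDF format error: header field 'number of data records' exceeds available data")
  data <- matrix(0, nch, ndr * spr)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  arr <- array(vals, dim = c(spr, nch, ndr))
  for (ch in seq_len(nch)) {
    data[ch, ] <- as.numeric(arr[, ch, ]) * scale[ch] +
      pmin_[ch] - dmin[ch] * scale[ch]
  }
  sensor_stream(data, fs, labels, kind = kind, units = units[1])
}
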