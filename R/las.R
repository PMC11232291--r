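# Minimal LAS (ASPRS) binary reader/writer: versions 1.2-1.4, point record
# formats 0-3 on read (x, y, z and intensity occupy the same leading bytes in
# all four); writes LAS 1.2, format 0, scale 0.001 m.

.las_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF"))
    stop(sprintf("'%s' is not a LAS file (bad signature)", path), call. = FALSE)
  seek(con, 24)
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  if (ver[1] != 1L || ver[2] < 2L)
    stop(sprintf("unsupported LAS version %d.%d (need 1.2+)", ver[1], ver[2]),
         call. = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", n = 1, size = 4)
  seek(con, 104)
  pdf <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
  reclen <- readBin(con, "integer", n = 1, size = 2, signed = FALSE)
  npts <- readBin(con, "integer", n = 1, size = 4)      # legacy count
  if (bitwAnd(pdf, 63L) > 3L)
    stop(sprintf("unsupported LAS point data format %d (need 0-3)", pdf),
         call. = FALSE)
  seek(con, 131)
  scales <- readBin(con, "double", n = 3, size = 8)
  offs <- readBin(con, "double", n = 3, size = 8)
  if (npts == 0L && ver[2] >= 4L) {
    seek(con, 247)
    lo <- readBin(con, "integer", n = 2, size = 4)      # uint64 as 2x uint32
    npts <- (if (lo[1] < 0) lo[1] + 2^32 else lo[1]) + lo[2] * 2^32
  }
  if (npts <= 0) stop("LAS file contains zero points", call. = FALSE)
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = npts * reclen)
  if (length(raw) < npts * reclen)
    stop("truncated LAS point data", call. = FALSE)
  rec <- matrix(raw, nrow = reclen)
  ints <- readBin(as.vector(rec[1:12, , drop = FALSE]), "integer",
                  n = 3L * npts, size = 4, endian = "little")
  xyz <- matrix(ints, ncol = 3, byrow = TRUE)
  pts <- cbind(xyz[, 1] * scales[1] + offs[1],
               xyz[, 2] * scales[2] + offs[2],
               xyz[, 3] * scales[3] + offs[3])
  intensity <- readBin(as.vector(rec[13:14, , drop = FALSE]), "integer",
                       n = npts, size = 2, signed = FALSE, endian = "little")
  list(points = pts, intensity = intensity)
}

.las_write <- function(points, path, intensity = NULL, scale = 0.001) {
  n <- nrow(points)
  offs <- c(0, 0, 0)
  ixyz <- round(sweep(points, 2, offs) / scale)
  if (any(abs(ixyz) > 2^31 - 1))
    stop("coordinates out of range for LAS scale 0.001", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)                 # source id, encoding
  writeBin(raw(16), con)                              # GUID
  writeBin(c(1L, 2L), con, size = 1)                  # version 1.2
  writeChar(formatC("rootqsm", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("rootqsm", width = 32, flag = "-"), con, 32, eos = NULL)
  writeBin(c(1L, 2024L), con, size = 2)               # day, year
  writeBin(227L, con, size = 2)                       # header size
  writeBin(227L, con, size = 4)                       # offset to point data
  writeBin(0L, con, size = 4)                         # n VLRs
  writeBin(0L, con, size = 1)                         # point format 0
  writeBin(20L, con, size = 2)                        # record length
  writeBin(as.integer(n), con, size = 4)              # n points
  writeBin(c(as.integer(n), 0L, 0L, 0L, 0L), con, size = 4)  # by return
  writeBin(rep(scale, 3), con, size = 8)
  writeBin(offs, con, size = 8)
  rng <- apply(points, 2, range)
  writeBin(c(rng[2, 1], rng[1, 1], rng[2, 2], rng[1, 2], rng[2, 3], rng[1, 3]),
           con, size = 8)
  # point records: xyz int32 (12) + intensity uint16 (2) + 6 bytes zero
  xyzraw <- writeBin(as.integer(t(ixyz)), raw(), size = 4, endian = "little")
  xyzm <- matrix(xyzraw, nrow = 12)
  intv <- if (is.null(intensity)) integer(n) else as.integer(round(intensity))
  intv[intv > 32767L] <- intv[intv > 32767L] - 65536L  # store as signed int16
  intraw <- matrix(writeBin(intv, raw(), size = 2, endian = "little"), nrow = 2)
  rec <- rbind(xyzm, intraw, matrix(as.raw(0), nrow = 6, ncol = n))
  writeBin(as.vector(rec), con)
  invisible(path)
}
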