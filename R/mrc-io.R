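#' Read an MRC image
#'
#' Minimal MRC2014 reader for 2-D micrographs and score maps.  Modes 0
#' (int8), 1 (int16), 2 (float32) and 6 (uint16) are supported; for
#' stacks (`nz > 1`) the first section is returned.  The pixel size is
#' taken from the header cell dimension divided by the grid size
#' (`cella.x / mx`); if the header carries no cell information the
#' pixel size defaults to 1 Angstrom.  Rows of the returned matrix
#' index y, columns index x (MRC stores x fastest).
#'
#' @param path path to an MRC file.
#' @return a [micrograph()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  if (fsize < 1024) stop("malformed header: file shorter than 1024 bytes")

  hdr_raw <- readBin(con, "raw", n = 1024L)
  # machine stamp at bytes 213-216 decides endianness
  endian <- if (as.integer(hdr_raw[213]) == 0x11) "big" else "little"
  ints <- readBin(hdr_raw, "integer", n = 256L, size = 4L, endian = endian)
  flts <- readBin(hdr_raw, "double", n = 256L, size = 4L, endian = endian)

  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]
  xlen <- flts[11]
  nsymbt <- ints[24]
  if (any(is.na(c(nx, ny, nz, mode))) ||
      nx < 1L || ny < 1L || nz < 1L || nx > 1e6 || ny > 1e6)
    stop("malformed header: inconsistent image dimensions")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("unsupported MRC mode: ", mode)
  if (is.na(nsymbt) || nsymbt < 0L || nsymbt > fsize)
    stop("malformed header: invalid extended header size")
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(mode)]
  need <- 1024 + as.numeric(nsymbt) + as.numeric(nx) * ny * nz * bytes_per
  if (fsize < need)
    stop("truncated data: file has ", fsize, " bytes, header implies >= ",
         need)

  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  n <- as.numeric(nx) * ny          # first section only
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = n, size = 1L,
                             signed = TRUE, endian = endian)),
    `1` = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = TRUE, endian = endian)),
    `2` = readBin(con, "double", n = n, size = 4L, endian = endian),
    `6` = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = FALSE, endian = endian)))
  if (length(vals) < n) stop("truncated data: could not read full section")
  pix <- if (!is.na(mx) && mx > 0L && is.finite(xlen) && xlen > 0)
    xlen / mx else 1.0
  # stored x fastest: fill columns of an nx x ny matrix, transpose to [y, x]
  micrograph(t(matrix(vals, nrow = nx, ncol = ny)),
             pixel_size_A = pix, source_name = basename(path))
}

#' Write an MRC image
#'
#' Writes a 2-D image as a single-section MRC2014 file in mode 2
#' (float32), little-endian, recording the pixel size in the header
#' cell dimensions.
#'
#' @param image a [micrograph()], [score_map()], or plain numeric
#'   matrix.
#' @param path output path.
#' @param pixel_size_A pixel size in Angstrom; defaults to the value
#'   carried by `image` when available.
#' @return invisibly, `path`.
#' @export
write_mrc <- function(image, path, pixel_size_A = NULL) {
  if (inherits(image, "micrograph")) {
    if (is.null(pixel_size_A)) pixel_size_A <- image$pixel_size_A
    m <- image$values
  } else if (inherits(image, "score_map")) {
    if (is.null(pixel_size_A))
      pixel_size_A <- image$pixel_size_A * image$downsample_factor
    m <- image$values
  } else {
    m <- as.matrix(image)
    if (is.null(pixel_size_A)) pixel_size_A <- 1.0
  }
  ny <- nrow(m); nx <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(c(nx, ny, 1L, 2L))                       # nx ny nz mode
  wi(c(0L, 0L, 0L))                           # nxstart..
  wi(c(nx, ny, 1L))                           # mx my mz
  wf(c(nx * pixel_size_A, ny * pixel_size_A, pixel_size_A))  # cella
  wf(c(90, 90, 90))                           # cellb
  wi(c(1L, 2L, 3L))                           # mapc mapr maps
  wf(c(min(m), max(m), mean(m)))              # dmin dmax dmean
  wi(c(0L, 0L))                               # ispg nsymbt
  writeBin(raw(100L), con)                    # extra (words 26-50)
  wf(c(0, 0, 0))                              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp LE
  wf(sd(as.numeric(m)))                       # rms
  wi(0L)                                      # nlabl
  writeBin(raw(800L), con)                    # labels
  # data: x fastest within a row of constant y
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}
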