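## Minimal MRC 2014 stack I/O (mode 2, 32-bit float, little endian).
## Header: 1024 bytes, 56 four-byte words + 800 bytes of labels; the pixel
## size is carried in CELLA / MX as usual.

#' Write an image stack as MRC 2014
#'
#' @param x A \code{defocus_series}, a list of matrices, a matrix, or a 3-D
#'   array (nx, ny, nz).
#' @param path Output file.
#' @param pixel_size Pixel size in Angstrom (taken from a
#'   \code{defocus_series} automatically).
#' @return \code{path}, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size = 1) {
  if (inherits(x, "defocus_series")) {
    pixel_size <- x$pixel_size
    x <- x$frames
  }
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  nx <- nrow(x[[1]]); ny <- ncol(x[[1]]); nz <- length(x)
  vals <- unlist(lapply(x, as.numeric), use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4,
                             endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4,
                             endian = "little")
  wi(c(nx, ny, nz, 2L))              # NX NY NZ MODE
  wi(c(0L, 0L, 0L))                  # NXSTART..
  wi(c(nx, ny, nz))                  # MX MY MZ
  wf(c(nx, ny, nz) * pixel_size)     # CELLA
  wf(c(90, 90, 90))                  # CELLB
  wi(c(1L, 2L, 3L))                  # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(c(0L, 0L))                      # ISPG NSYMBT
  wi(integer(25))                    # EXTRA
  wf(c(0, 0, 0))                     # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))                # RMS
  wi(0L)                             # NLABL
  writeBin(raw(800), con)            # labels
  wf(vals)
  invisible(path)
}

#' Read an MRC 2014 stack (mode 2)
#'
#' @param path Input file.
#' @return List with \code{data} (list of nx-by-ny matrices),
#'   \code{pixel_size} (Angstrom), and \code{dim}.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only MRC mode 2 (float32) is supported, got ", mode)
  ri(3)                # NXSTART
  mx <- ri(3)          # MX MY MZ
  cella <- rf(3)
  seek(con, 1024)
  n <- prod(dims)
  vals <- rf(n)
  frames <- lapply(seq_len(dims[3]), function(i)
    matrix(vals[((i - 1) * dims[1] * dims[2] + 1):(i * dims[1] * dims[2])],
           dims[1], dims[2]))
  list(data = frames, pixel_size = cella[1] / mx[1], dim = dims)
}
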