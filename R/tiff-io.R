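#' Write a 3D stack as a multi-page TIFF
#'
#' Writes one 32-bit-float page per z-plane (little-endian, uncompressed
#' baseline TIFF), the interchange format for microscopy z-stacks. A JSON
#' sidecar (same path with `.json` appended) records the optical
#' configuration and seed when available, so a stack can be re-associated
#' with the simulation that produced it.
#'
#' @param stack Numeric array `c(ny, nx, nz)` or matrix.
#' @param path Output file path.
#' @param metadata Optional list serialised to the JSON sidecar; when
#'   `NULL`, the stack's `config` attribute (if any) is used.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = NULL) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  stopifnot(length(dim(stack)) == 3)
  d <- dim(stack)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w2(42L)
  header_size <- 8L
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_bytes <- ny * nx * 4L
  # layout: header | IFD_1 .. IFD_nz | data_1 .. data_nz
  ifd_offset <- function(i) header_size + (i - 1L) * ifd_size
  data_offset <- function(i) header_size + nz * ifd_size + (i - 1L) * page_bytes
  w4(ifd_offset(1L))
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(nz)) {
    w2(n_entries)
    entry(256L, 4L, 1L, nx)              # ImageWidth
    entry(257L, 4L, 1L, ny)              # ImageLength
    entry(258L, 3L, 1L, 32L)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression: none
    entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_offset(i))  # StripOffsets (single strip)
    entry(279L, 4L, 1L, page_bytes)      # StripByteCounts
    entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
    w4(if (i < nz) ifd_offset(i + 1L) else 0L)
  }
  for (i in seq_len(nz)) {
    # TIFF stores rows (y) contiguously: transpose the (y, x) plane
    writeBin(as.numeric(t(stack[, , i])), con, size = 4, endian = "little")
  }
  meta <- metadata
  if (is.null(meta)) {
    cfg <- attr(stack, "config")
    if (!is.null(cfg)) meta <- unclass(cfg)
  }
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads uncompressed little-endian TIFF stacks with one page per z-plane,
#' 32-bit IEEE float or 16/8-bit unsigned integer samples (the formats
#' microscope acquisition software typically writes). 32-bit float stacks
#' round-trip bit exactly through [write_stack()]. If a JSON sidecar is
#' present its contents are attached as the `metadata` attribute; a
#' missing sidecar is not an error (a warning-level message is logged).
#'
#' @param path TIFF file path.
#' @param quiet Suppress the missing-sidecar message.
#' @return Numeric array `c(ny, nx, nz)` with attribute `metadata`.
#' @export
read_stack <- function(path, quiet = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file", call. = FALSE))
  r2 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                           endian = endian)
  r4 <- function() readBin(con, "integer", 1, size = 4, endian = endian)
  if (r2() != 42L) stop("not a TIFF file", call. = FALSE)
  next_ifd <- r4()
  planes <- list()
  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n <- r2()
    tags <- list()
    for (i in seq_len(n)) {
      tag <- r2(); type <- r2(); count <- r4()
      val_pos <- seek(con)
      value <- if (type == 3L) r2() else r4()
      seek(con, val_pos + 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = value, pos = val_pos)
    }
    next_ifd <- r4()
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop("missing TIFF tag ", tag, call. = FALSE)
        return(default)
      }
      t$value
    }
    nx <- need(256L); ny <- need(257L)
    bits <- need(258L, 1L)
    if (need(259L, 1L) != 1L)
      stop("compressed TIFF not supported", call. = FALSE)
    fmt <- need(339L, 1L)
    # strip offsets/counts may be arrays stored out of line
    read_vec <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (t$count == 1L) return(t$value)
      seek(con, t$value)
      readBin(con, "integer", t$count, size = if (t$type == 3L) 2 else 4,
              signed = t$type != 3L, endian = endian)
    }
    offs <- read_vec(273L)
    cnts <- read_vec(279L)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      nsamp <- cnts[s] / (bits / 8)
      vals <- c(vals, if (fmt == 3L && bits == 32L) {
        readBin(con, "numeric", nsamp, size = 4, endian = endian)
      } else if (fmt == 1L && bits == 16L) {
        readBin(con, "integer", nsamp, size = 2, signed = FALSE,
                endian = endian)
      } else if (fmt == 1L && bits == 8L) {
        as.numeric(readBin(con, "raw", nsamp))
      } else {
        stop("unsupported TIFF sample format (", bits, "-bit, format ",
             fmt, ")", call. = FALSE)
      })
    }
    if (length(vals) != nx * ny)
      stop("inconsistent page shapes in TIFF", call. = FALSE)
    planes[[length(planes) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
  }
  shapes <- vapply(planes, dim, integer(2))
  if (length(planes) > 1 && any(shapes != shapes[, 1]))
    stop("inconsistent page shapes in TIFF", call. = FALSE)
  out <- array(unlist(planes), c(dim(planes[[1]]), length(planes)))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "metadata") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    attr(out, "metadata") <- NULL
    if (!quiet) message("no JSON sidecar found for ", path,
                        "; stack loaded without metadata")
  }
  out
}
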