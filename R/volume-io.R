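#' Read a volumetric grid from MRC or multi-page TIFF
#'
#' Volumes are returned in `(z, y, x)` axis order with 1-based voxel
#' coordinates. For MRC the on-disk fastest axis (x) becomes the third array
#' index; for TIFF each page is one z-slice. When the file carries no usable
#' voxel-size metadata (TIFF always, MRC with a zero cell), the size defaults
#' to 35 nm isotropic and a message is emitted.
#'
#' @param path file to read.
#' @param format_hint `"mrc"`, `"tiff"` or `NULL` (guess from the file
#'   extension, falling back to the MRC magic).
#' @param kind `"auto"` (default), `"tomogram"`, `"semantic_mask"` or
#'   `"instance_mask"`. With `"auto"`, integer-valued content in \{0,1\}
#'   becomes a semantic mask, other non-negative integer content an instance
#'   mask, and anything else a tomogram. Requesting a mask kind for
#'   fractional-valued content is a validation error.
#' @return A [tomogram()], [semantic_mask()] or [instance_mask()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format_hint = NULL,
                        kind = c("auto", "tomogram", "semantic_mask", "instance_mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  fmt <- if (is.null(format_hint)) guess_format(path) else match.arg(format_hint, c("mrc", "tiff"))
  raw <- switch(fmt, mrc = read_mrc(path), tiff = read_tiff_volume(path))
  finish_volume(raw$data, raw$voxel_size, raw$origin, kind, path)
}

#' Write a volumetric grid to MRC or multi-page TIFF
#'
#' Tomograms are stored as float32 (MRC mode 2 / 32-bit float TIFF); masks as
#' unsigned 16-bit integers (MRC mode 6 / 16-bit TIFF), which is lossless for
#' instance counts far below 65535. Voxel size and origin are stored in the
#' MRC header; TIFF carries no such metadata, so they are lost on a TIFF
#' round trip (the reader then defaults to 35 nm).
#'
#' @param vol an `sxt_volume`.
#' @param path destination file; its directory must exist.
#' @param format `"auto"` (from extension), `"mrc"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "mrc", "tiff")) {
  stopifnot(inherits(vol, "sxt_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, must_exist = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory '", dir, "' does not exist", call. = FALSE)
  is_mask <- inherits(vol, "semantic_mask") || inherits(vol, "instance_mask")
  if (is_mask && max(vol) > 65535) stop("mask labels exceed 16-bit range", call. = FALSE)
  switch(format,
         mrc  = write_mrc(vol, path, is_mask),
         tiff = write_tiff_volume(vol, path, is_mask))
  invisible(path)
}

guess_format <- function(path, must_exist = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map")) return("mrc")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (must_exist && file.exists(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    hdr <- readBin(con, "raw", 212)
    if (length(hdr) == 212 && rawToChar(hdr[209:211]) == "MAP") return("mrc")
    return("tiff")
  }
  stop("cannot determine volume format of '", path,
       "'; use an .mrc/.tif extension or format_hint", call. = FALSE)
}

finish_volume <- function(data, vs, origin, kind, path) {
  if (is.null(vs)) {
    message("no voxel-size metadata in '", basename(path), "'; assuming 35 nm isotropic")
    vs <- c(35, 35, 35)
  }
  vals <- as.vector(data)
  if (any(!is.finite(vals))) stop("non-finite voxel values in '", path, "'", call. = FALSE)
  integral <- all(vals == round(vals))
  if (kind == "auto") {
    kind <- if (integral && all(vals %in% c(0, 1))) "semantic_mask"
            else if (integral && all(vals >= 0)) "instance_mask"
            else "tomogram"
  }
  if (kind != "tomogram" && !integral) {
    stop("fractional voxel values in '", path, "' cannot form a ", kind, call. = FALSE)
  }
  if (kind != "tomogram") storage.mode(data) <- "integer"
  switch(kind,
         tomogram = tomogram(data, vs, origin),
         semantic_mask = semantic_mask(data, vs, origin),
         instance_mask = instance_mask(data, vs, origin))
}

# ---- MRC2014 (little endian, modes 0/1/2/6) --------------------------------
# 1024-byte header; data stored x-fastest, then y, then z.

read_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  ints1 <- readBin(con, integer(), 10, size = 4, endian = "little") # nx..mz
  cella <- readBin(con, numeric(), 3, size = 4, endian = "little")
  readBin(con, numeric(), 3, size = 4, endian = "little")           # cellb
  readBin(con, integer(), 3, size = 4, endian = "little")           # mapc/r/s
  readBin(con, numeric(), 3, size = 4, endian = "little")           # dmin/max/mean
  readBin(con, integer(), 2, size = 4, endian = "little")           # ispg, nsymbt
  seek(con, 1024)
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  if (any(c(nx, ny, nz) < 1)) stop("invalid MRC dimensions", call. = FALSE)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, integer(), n, size = 1, signed = TRUE),
    "1" = readBin(con, integer(), n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, numeric(), n, size = 4, endian = "little"),
    "6" = readBin(con, integer(), n, size = 2, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE))
  if (length(vals) < n) stop("truncated MRC data in '", path, "'", call. = FALSE)
  a <- aperm(array(vals, c(nx, ny, nz)), c(3, 2, 1))   # -> (z, y, x)
  mx <- ints1[8:10]                                    # (mx, my, mz)
  vs <- if (all(mx > 0) && all(cella > 0)) rev(cella / mx) / 10 else NULL  # A -> nm, (z,y,x)
  origin <- rev(ints1[5:7]) + 1L                       # nxstart 0-based -> 1-based (z,y,x)
  list(data = a, voxel_size = vs, origin = origin)
}

write_mrc <- function(vol, path, is_mask) {
  d <- dim(vol)                      # (z, y, x)
  a <- aperm(as_bare_array(vol), c(3, 2, 1))
  vs <- attr(vol, "voxel_size")      # nm, (z, y, x)
  origin <- attr(vol, "origin")
  mode <- if (is_mask) 6L else 2L
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d[3], d[2], d[1], mode))                 # nx ny nz mode
  wi(rev(origin) - 1L)                          # nxstart nystart nzstart
  wi(c(d[3], d[2], d[1]))                       # mx my mz
  wf(c(d[3], d[2], d[1]) * rev(vs) * 10)        # cella (Angstrom)
  wf(c(90, 90, 90))                             # cellb
  wi(c(1, 2, 3))                                # mapc mapr maps
  wf(c(min(vol), max(vol), mean(vol)))          # dmin dmax dmean
  wi(c(1, 0))                                   # ispg, nsymbt
  wi(rep(0L, 25))                               # extra
  wf(c(0, 0, 0))                                # origin (float, unused here)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little endian
  wf(stats::sd(as.vector(vol)))                 # rms
  wi(0L)                                        # nlabl
  writeBin(raw(800), con)                       # labels
  v <- as.vector(a)
  if (mode == 6L) {
    # writeBin has no unsigned 16-bit: values < 65536 fit the signed
    # representation after wrapping
    v <- as.integer(v); v[v > 32767] <- v[v > 32767] - 65536L
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
}

# ---- multi-page TIFF -------------------------------------------------------

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) is.matrix(p), logical(1)))) {
    stop("'", path, "' has non-grayscale pages; expected one 2D slice per page",
         call. = FALSE)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF pages of '", path, "' differ in shape", call. = FALSE)
  }
  a <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    # 8/16-bit pages are unsigned integers rescaled to [0,1] by the reader;
    # undo that scaling losslessly. 32-bit pages are floats, used as read
    # (this package writes tomograms as 32-bit float, masks as 16-bit).
    bps <- attr(p, "bits.per.sample") %||% 8L
    if (bps < 32L) p <- round(p * (2^bps - 1))
    a[k, , ] <- p
  }
  list(data = a, voxel_size = NULL, origin = c(1L, 1L, 1L))
}

write_tiff_volume <- function(vol, path, is_mask) {
  d <- dim(vol)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- as_bare_array(vol)[k, , , drop = TRUE]
    dim(m) <- d[2:3]
    if (is_mask) m / 65535 else m
  })
  if (is_mask) {
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
}
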