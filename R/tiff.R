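# Minimal baseline TIFF codec: uncompressed, chunky planar layout, one
# z-slice per page, 1 or 3 samples per pixel.  Written files are
# little-endian with float64 sample format by default so that read/write
# round-trips are bit-exact; 8-bit export applies a documented affine
# quantisation.  The reader additionally accepts big-endian files and
# uint8/uint16/float32/float64 samples (what common writers emit for
# microscopy stacks).

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

tiff_read_header <- function(con) {
  magic <- readBin(con, "raw", 2)
  order_chr <- rawToChar(magic)
  if (order_chr == "II") endian <- "little"
  else if (order_chr == "MM") endian <- "big"
  else stop("not a TIFF file (bad byte-order mark)")
  forty_two <- readBin(con, "integer", 1, size = 2, endian = endian,
                       signed = FALSE)
  if (forty_two != 42L) stop("not a TIFF file (bad magic number)")
  first_ifd <- readBin(con, "integer", 1, size = 4, endian = endian)
  list(endian = endian, first_ifd = first_ifd)
}

tiff_read_entry_values <- function(con, type, count, raw4, endian) {
  size <- TIFF_TYPE_SIZES[type]
  total <- size * count
  if (total <= 4) {
    vals_con <- rawConnection(raw4)
    on.exit(close(vals_con))
  } else {
    oc <- rawConnection(raw4)
    offset <- readBin(oc, "integer", 1, size = 4, endian = endian)
    close(oc)
    seek(con, offset)
    vals_con <- con
  }
  if (type %in% c(3L, 8L)) {      # SHORT / SSHORT
    readBin(vals_con, "integer", count, size = 2, endian = endian,
            signed = type == 8L)
  } else if (type %in% c(4L, 9L)) { # LONG / SLONG
    readBin(vals_con, "integer", count, size = 4, endian = endian)
  } else if (type == 1L) {          # BYTE
    as.integer(readBin(vals_con, "raw", count))
  } else {
    NULL                            # types we do not need
  }
}

tiff_read_ifds <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- tiff_read_header(con)
  ifds <- list()
  next_ifd <- hdr$first_ifd
  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n_entries <- readBin(con, "integer", 1, size = 2, endian = hdr$endian,
                         signed = FALSE)
    entries_raw <- readBin(con, "raw", n_entries * 12L)
    after_entries <- seek(con, NA)
    next_ifd <- readBin(con, "integer", 1, size = 4, endian = hdr$endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      er <- entries_raw[((i - 1L) * 12L + 1L):(i * 12L)]
      ec <- rawConnection(er)
      tag <- readBin(ec, "integer", 1, size = 2, endian = hdr$endian,
                     signed = FALSE)
      type <- readBin(ec, "integer", 1, size = 2, endian = hdr$endian,
                      signed = FALSE)
      count <- readBin(ec, "integer", 1, size = 4, endian = hdr$endian)
      raw4 <- readBin(ec, "raw", 4)
      close(ec)
      if (type >= 1L && type <= 12L)
        tags[[as.character(tag)]] <-
          tiff_read_entry_values(con, type, count, raw4, hdr$endian)
    }
    ifds[[length(ifds) + 1L]] <- tags
  }
  list(endian = hdr$endian, ifds = ifds)
}

tiff_tag <- function(tags, id, default = NULL) {
  v <- tags[[as.character(id)]]
  if (is.null(v)) default else v
}

#' Inspect a multi-page TIFF without reading pixel data
#'
#' @param path path to a TIFF file.
#' @return list with `pages`, `width`, `height`, `samples_per_pixel`,
#'   `bits_per_sample`, `sample_format`.
#' @export
tiff_info <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  meta <- tiff_read_ifds(path)
  first <- meta$ifds[[1]]
  list(pages = length(meta$ifds),
       width = tiff_tag(first, 256),
       height = tiff_tag(first, 257),
       samples_per_pixel = tiff_tag(first, 277, 1L),
       bits_per_sample = tiff_tag(first, 258, 1L)[1],
       sample_format = tiff_tag(first, 339, 1L)[1])
}

tiff_read_page <- function(con, tags, endian) {
  width <- tiff_tag(tags, 256)
  height <- tiff_tag(tags, 257)
  spp <- tiff_tag(tags, 277, 1L)
  bits <- tiff_tag(tags, 258, 1L)[1]
  fmt <- tiff_tag(tags, 339, 1L)[1]
  comp <- tiff_tag(tags, 259, 1L)
  planar <- tiff_tag(tags, 284, 1L)
  if (comp != 1L) stop("unsupported TIFF compression scheme ", comp)
  if (planar != 1L) stop("unsupported TIFF planar configuration ", planar)
  offsets <- tiff_tag(tags, 273)
  counts <- tiff_tag(tags, 279)
  if (is.null(offsets)) stop("TIFF page has no strip offsets")
  raw_data <- raw(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    raw_data <- c(raw_data, readBin(con, "raw", counts[i]))
  }
  n <- as.integer(width) * as.integer(height) * as.integer(spp)
  rc <- rawConnection(raw_data)
  on.exit(close(rc))
  vals <- if (fmt == 3L && bits == 32L) {
    readBin(rc, "double", n, size = 4, endian = endian)
  } else if (fmt == 3L && bits == 64L) {
    readBin(rc, "double", n, size = 8, endian = endian)
  } else if (fmt == 1L && bits == 8L) {
    as.numeric(readBin(rc, "integer", n, size = 1, endian = endian,
                       signed = FALSE))
  } else if (fmt == 1L && bits == 16L) {
    as.numeric(readBin(rc, "integer", n, size = 2, endian = endian,
                       signed = FALSE))
  } else {
    stop("unsupported TIFF sample format: format ", fmt, ", ", bits, " bits")
  }
  # sample order within a page is (c, x, y) fastest-first
  aperm(array(vals, c(spp, width, height)), c(3L, 2L, 1L))
}

#' Read a multi-page TIFF as a z-stack
#'
#' Pages are z-slices; samples per pixel are channels.  The returned volume
#' has `value_range = "raw"` and axis order `(z, y, x, c)`.
#'
#' @param path path to an uncompressed multi-page TIFF.
#' @return a [zstack].
#' @export
read_zstack <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  meta <- tiff_read_ifds(path)
  if (length(meta$ifds) == 0L) stop("TIFF has no pages: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  pages <- lapply(meta$ifds, function(tags)
    tiff_read_page(con, tags, meta$endian))
  d1 <- dim(pages[[1]])
  ok <- vapply(pages, function(p) identical(dim(p), d1), logical(1))
  if (!all(ok)) stop("TIFF pages have inconsistent dimensions: ", path)
  data <- array(0, c(length(pages), d1))
  for (z in seq_along(pages)) data[z, , , ] <- pages[[z]]
  zstack(data, "raw")
}

tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw, raw(4 - length(value_raw)))
}

tiff_short_val <- function(x) {
  writeBin(as.integer(x), raw(), size = 2, endian = "little")
}
tiff_long_val <- function(x) {
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

#' Write a z-stack as a multi-page TIFF
#'
#' Default export is float64 sample format, which round-trips bit-exactly
#' through [read_zstack].  With `bits = 8` the declared value range is
#' affinely mapped onto `[0, 255]` and rounded: `unit_signed` maps
#' `[-1, 1]`, `unit` maps `[0, 1]`, and `raw` maps the volume's own
#' min/max (a constant raw volume maps to 0).
#'
#' @param volume a [zstack].
#' @param path output path.
#' @param bits 64 (float, lossless) or 8 (quantised export).
#' @return `path`, invisibly.
#' @export
write_zstack <- function(volume, path, bits = 64) {
  validate_zstack(volume)
  if (!bits %in% c(8, 64)) stop("bits must be 8 or 64")
  d <- dim(volume$data)
  nz <- d[1]; h <- d[2]; w <- d[3]; spp <- d[4]
  data <- volume$data
  if (bits == 8) {
    rng <- switch(volume$value_range,
                  unit_signed = c(-1, 1),
                  unit = c(0, 1),
                  raw = range(data))
    if (rng[2] - rng[1] <= 0) {
      data <- array(0, d)
    } else {
      data <- round((data - rng[1]) / (rng[2] - rng[1]) * 255)
    }
  }
  bytes_per <- if (bits == 8) 1L else 8L
  strip_size <- as.integer(h * w * spp * bytes_per)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write TIFF: ", path))
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_start <- 8L
  first_ifd <- data_start + nz * strip_size
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    page <- aperm(array(data[z, , , ], c(h, w, spp)), c(3L, 2L, 1L))
    if (bits == 8) {
      writeBin(as.integer(page), con, size = 1, endian = "little")
    } else {
      writeBin(as.numeric(page), con, size = 8, endian = "little")
    }
  }
  # IFDs: entries must be in ascending tag order; out-of-line value blocks
  # (BitsPerSample / SampleFormat for RGB) follow each IFD.
  needs_extra <- spp == 3L
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  extra_size <- if (needs_extra) 2L * (2L * spp) else 0L
  pos <- first_ifd
  for (z in seq_len(nz)) {
    ifd_pos <- pos
    extra_pos <- ifd_pos + ifd_size
    next_ifd <- if (z < nz) extra_pos + extra_size else 0L
    strip_off <- data_start + (z - 1L) * strip_size
    fmt <- if (bits == 8) 1L else 3L
    entries <- list(
      tiff_entry(256, 4, 1, tiff_long_val(w)),
      tiff_entry(257, 4, 1, tiff_long_val(h)),
      if (needs_extra)
        tiff_entry(258, 3, spp, tiff_long_val(extra_pos))
      else tiff_entry(258, 3, 1, tiff_short_val(bits)),
      tiff_entry(259, 3, 1, tiff_short_val(1)),
      tiff_entry(262, 3, 1, tiff_short_val(if (spp == 3L) 2 else 1)),
      tiff_entry(273, 4, 1, tiff_long_val(strip_off)),
      tiff_entry(277, 3, 1, tiff_short_val(spp)),
      tiff_entry(278, 4, 1, tiff_long_val(h)),
      tiff_entry(279, 4, 1, tiff_long_val(strip_size)),
      if (needs_extra)
        tiff_entry(339, 3, spp, tiff_long_val(extra_pos + 2L * spp))
      else tiff_entry(339, 3, 1, tiff_short_val(fmt)))
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    if (needs_extra) {
      writeBin(rep(as.integer(bits), spp), con, size = 2, endian = "little")
      writeBin(rep(as.integer(fmt), spp), con, size = 2, endian = "little")
    }
    pos <- extra_pos + extra_size
  }
  invisible(path)
}
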