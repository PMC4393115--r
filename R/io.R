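## File formats.
##
## TIFF support is a deliberately small baseline codec (little-endian,
## uncompressed, single-channel grayscale, multi-page, uint16 or float32)
## written with readBin/writeBin: no TIFF-capable R package is available in
## the target environment, and these are the only flavors the pipeline
## needs (raw ADU movies and SR float images).  Images follow the package
## convention matrix[ix, iy]; TIFF row j of a page is matrix column j + 1.

SCHEMA_COLUMNS <- c("frame", "x_nm", "y_nm", "x_px", "y_px", "photons", "bg",
                    "sigma_x_nm", "sigma_y_nm", "pvalue", "accepted")

#' Write an image stack as a multi-page TIFF
#'
#' @param stack Matrix or 3D array `(nx, ny, n_frames)`.
#' @param path Output file.
#' @param type `"uint16"` (raw ADU movies) or `"float32"` (SR images).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, type = c("uint16", "float32")) {
  type <- match.arg(type)
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]; nf <- dim(stack)[3]
  bps <- if (type == "uint16") 2L else 4L
  fmt <- if (type == "uint16") 1L else 3L
  if (type == "uint16" && (min(stack) < 0 || max(stack) > 65535))
    stop("uint16 TIFF requires values in [0, 65535]")
  con <- file(path, "wb")
  on.exit(close(con))
  # layout per page: [strip data][IFD]
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  strip_size <- nx * ny * bps
  page_size <- strip_size + ifd_size
  first_ifd <- 8L + strip_size
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  tag <- function(id, typ, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L) {  # SHORT: left-justified in the 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (f in seq_len(nf)) {
    page_off <- 8L + (f - 1L) * page_size
    v <- stack[, , f]
    if (type == "uint16") {
      iv <- as.integer(round(v))
      b <- raw(2L * length(iv))
      b[seq(1, length(b), 2)] <- as.raw(iv %% 256L)
      b[seq(2, length(b), 2)] <- as.raw(iv %/% 256L)
      writeBin(b, con)
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
    writeBin(as.integer(n_tags), con, size = 2, endian = "little")
    tag(256, 3, 1, nx)                      # ImageWidth
    tag(257, 3, 1, ny)                      # ImageLength
    tag(258, 3, 1, bps * 8L)                # BitsPerSample
    tag(259, 3, 1, 1)                       # Compression: none
    tag(262, 3, 1, 1)                       # Photometric: BlackIsZero
    tag(273, 4, 1, page_off)                # StripOffsets
    tag(278, 3, 1, ny)                      # RowsPerStrip
    tag(279, 4, 1, strip_size)              # StripByteCounts
    tag(339, 3, 1, fmt)                     # SampleFormat
    nxt <- if (f < nf) page_off + page_size + strip_size else 0L  # next IFD
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF written for/by this package
#'
#' Supports baseline little- or big-endian, uncompressed, single-channel
#' grayscale TIFF with 16-bit unsigned or 32-bit float samples.
#'
#' @param path TIFF file.
#' @return 3D array `(nx, ny, n_frames)` (integer for uint16, numeric for
#'   float32).
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  bo <- rawToChar(raw_all[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file")
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  magic <- rd(2, "integer", 1, 2)
  if (magic != 42) stop("not a TIFF file")
  ifd_off <- rd(4, "integer", 1, 4)
  frames <- list()
  while (ifd_off != 0) {
    n_tags <- rd(ifd_off, "integer", 1, 2)
    tags <- list()
    for (k in seq_len(n_tags)) {
      toff <- ifd_off + 2 + (k - 1) * 12
      id <- rd(toff, "integer", 1, 2, signed = FALSE)
      typ <- rd(toff + 2, "integer", 1, 2)
      cnt <- rd(toff + 4, "integer", 1, 4)
      val <- if (typ == 3) {
        if (cnt <= 2) rd(toff + 8, "integer", cnt, 2, signed = FALSE)
        else rd(rd(toff + 8, "integer", 1, 4), "integer", cnt, 2, signed = FALSE)
      } else {
        if (cnt <= 1) rd(toff + 8, "integer", 1, 4)
        else rd(rd(toff + 8, "integer", 1, 4), "integer", cnt, 4)
      }
      tags[[as.character(id)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- g(256); h <- g(257)
    bits <- g(258, 1); comp <- g(259, 1); fmt <- g(339, 1)
    if (comp != 1) stop("unsupported TIFF compression: ", comp)
    if (!(bits == 16 && fmt == 1) && !(bits == 32 && fmt == 3))
      stop("unsupported TIFF bit depth/sample format: ", bits, "/", fmt)
    offs <- g(273); counts <- g(279, w * h * bits / 8)
    vals <- unlist(lapply(seq_along(offs), function(s) {
      n <- counts[s] / (bits / 8)
      if (bits == 16) rd(offs[s], "integer", n, 2, signed = FALSE)
      else rd(offs[s], "numeric", n, 4)
    }))
    frames[[length(frames) + 1]] <- matrix(vals, nrow = w, ncol = h)
    ifd_off <- rd(ifd_off + 2 + n_tags * 12, "integer", 1, 4)
  }
  arr <- array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
  if (is.integer(frames[[1]])) storage.mode(arr) <- "integer"
  arr
}

#' Read/write localization tables as delimited text
#'
#' The on-disk schema is a comma-separated table with the fixed header
#' `frame, x_nm, y_nm, x_px, y_px, photons, bg, sigma_x_nm, sigma_y_nm,
#' pvalue, accepted`; extra columns are preserved.  Values round-trip to
#' better than 1e-6 nm.
#'
#' @param table A localization table.
#' @param path File path.
#' @return `write_localizations` returns `path` invisibly;
#'   `read_localizations` returns a `localization_table`.
#' @export
write_localizations <- function(table, path) {
  miss <- setdiff(SCHEMA_COLUMNS, names(table))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  miss <- setdiff(SCHEMA_COLUMNS, names(tab))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  tab$frame <- as.integer(tab$frame)
  tab$accepted <- as.logical(tab$accepted)
  if ("converged" %in% names(tab)) tab$converged <- as.logical(tab$converged)
  class(tab) <- c("localization_table", "data.frame")
  tab
}

#' Read/write segment lists
#'
#' Delimited text with columns `x1, y1, x2, y2` (nm), one segment per row.
#'
#' @param segments List of [segment_spec()]s (write) or file path (read).
#' @param path File path.
#' @param ... Extra arguments passed to [segment_spec()] when reading.
#' @return A list of `segment_spec`s (read); `path` invisibly (write).
#' @export
write_segments <- function(segments, path) {
  df <- do.call(rbind, lapply(segments, function(s)
    data.frame(x1 = s$x1, y1 = s$y1, x2 = s$x2, y2 = s$y2)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path, ...) {
  df <- as.data.frame(data.table::fread(path))
  lapply(seq_len(nrow(df)), function(i)
    segment_spec(df$x1[i], df$y1[i], df$x2[i], df$y2[i], ...))
}
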