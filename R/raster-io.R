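#' Read a raster grid from disk
#'
#' Two dialects are supported: ESRI ASCII grid (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header) and a plain single-band GeoTIFF
#' (uncompressed IEEE float64, one strip, `ModelPixelScale` +
#' `ModelTiepoint` georeference — exactly what [write_raster()] emits; other
#' TIFF variants are rejected with a format error). ASCII round-trips are
#' bit-exact; GeoTIFF stores IEEE doubles so round-trips are exact too.
#'
#' @param path File to read.
#' @param dialect `"auto"` (by extension: `.asc` vs `.tif`/`.tiff`),
#'   `"ascii"` or `"geotiff"`.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, dialect = c("auto", "ascii", "geotiff")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") dialect <- guess_dialect(path)
  switch(dialect,
    ascii = read_ascii_grid(path),
    geotiff = read_geotiff(path)
  )
}

#' Write a raster grid to disk
#'
#' @param grid A [raster_grid()].
#' @param path Output file.
#' @param dialect See [read_raster()].
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, dialect = c("auto", "ascii", "geotiff")) {
  stopifnot(is_raster_grid(grid))
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  switch(dialect,
    ascii = write_ascii_grid(grid, path),
    geotiff = write_geotiff(grid, path)
  )
  invisible(path)
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "geotiff" else "ascii"
}

# ---- ESRI ASCII grid ------------------------------------------------------

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    stop("ascii-grid format error: empty file ", path, call. = FALSE)
  }
  hdr <- list()
  n_hdr <- 0L
  for (i in seq_len(min(7L, length(lines)))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c(
      "ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value"
    )) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (length(parts) < 2 || is.na(val)) {
        stop("ascii-grid format error: unreadable value for header field '",
          key, "'",
          call. = FALSE
        )
      }
      hdr[[key]] <- val
      n_hdr <- i
    } else {
      break
    }
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]])) {
      stop("ascii-grid format error: missing header field '", req, "'",
        call. = FALSE
      )
    }
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- paste(lines[-seq_len(n_hdr)], collapse = "\n")
  vals <- scan(text = body, what = double(), quiet = TRUE)
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (length(vals) != nr * nc) {
    stop(sprintf(
      "ascii-grid format error: expected %d values (%d x %d), found %d",
      nr * nc, nr, nc, length(vals)
    ), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

write_ascii_grid <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\ncellsize %.17g\nNODATA_value -9999\n",
    grid$n_cols, grid$n_rows, grid$x_origin, grid$y_origin, grid$cell_size
  )
  writeChar(hdr, con, eos = NULL)
  vals <- grid$values
  vals[is.na(vals)] <- -9999
  rows <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeChar(paste0(paste(rows, collapse = "\n"), "\n"), con, eos = NULL)
}

# ---- minimal GeoTIFF (single band, float64, one strip) --------------------

tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

read_geotiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readBin(con, "raw", 2)
  endian <- if (identical(rawToChar(order_bytes), "II")) {
    "little"
  } else if (identical(rawToChar(order_bytes), "MM")) {
    "big"
  } else {
    stop("geotiff format error: bad byte-order mark", call. = FALSE)
  }
  magic <- readBin(con, "integer", 1, size = 2, endian = endian, signed = FALSE)
  if (magic != 42L) stop("geotiff format error: bad magic number", call. = FALSE)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, endian = endian, signed = FALSE)
  entries <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, endian = endian, signed = FALSE)
    type <- readBin(con, "integer", 1, size = 2, endian = endian, signed = FALSE)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    raw_val <- readBin(con, "raw", 4)
    entries[[as.character(tag)]] <- list(type = type, count = count, raw = raw_val)
  }
  read_entry <- function(tag, field) {
    e <- entries[[as.character(tag)]]
    if (is.null(e)) {
      stop("geotiff format error: missing required tag '", field, "'",
        call. = FALSE
      )
    }
    sz <- tiff_type_size[[as.character(e$type)]]
    if (is.null(sz)) {
      stop("geotiff format error: unsupported type for tag '", field, "'",
        call. = FALSE
      )
    }
    total <- sz * e$count
    get_vals <- function(connection) {
      if (e$type == 2) {
        chars <- readBin(connection, "raw", e$count)
        return(rawToChar(chars[chars != as.raw(0)]))
      }
      what <- if (e$type %in% c(11, 12)) "double" else "integer"
      signed <- !(e$type %in% c(1, 3))
      readBin(connection, what, e$count, size = sz, endian = endian, signed = signed)
    }
    if (total <= 4) {
      tmp <- rawConnection(e$raw)
      on.exit(close(tmp), add = TRUE)
      get_vals(tmp)
    } else {
      off_con <- rawConnection(e$raw)
      off <- readBin(off_con, "integer", 1, size = 4, endian = endian)
      close(off_con)
      seek(con, off)
      get_vals(con)
    }
  }
  width <- read_entry(256, "ImageWidth")
  height <- read_entry(257, "ImageLength")
  bits <- read_entry(258, "BitsPerSample")
  compression <- read_entry(259, "Compression")
  sample_format <- if (!is.null(entries[["339"]])) read_entry(339, "SampleFormat") else 1L
  if (compression != 1L) {
    stop("geotiff format error: only uncompressed TIFF is supported",
      call. = FALSE
    )
  }
  if (!(bits[1] == 64 && sample_format[1] == 3)) {
    stop("geotiff format error: only IEEE float64 samples are supported",
      call. = FALSE
    )
  }
  strip_offsets <- read_entry(273, "StripOffsets")
  if (length(strip_offsets) != 1L) {
    stop("geotiff format error: multi-strip files are not supported",
      call. = FALSE
    )
  }
  scale <- read_entry(33550, "ModelPixelScale")
  tiepoint <- read_entry(33922, "ModelTiepoint")
  seek(con, strip_offsets)
  vals <- readBin(con, "double", width * height, size = 8, endian = endian)
  if (length(vals) != width * height) {
    stop("geotiff format error: truncated pixel data", call. = FALSE)
  }
  nodata <- NULL
  if (!is.null(entries[["42113"]])) {
    nodata <- suppressWarnings(as.numeric(read_entry(42113, "GDAL_NODATA")))
  }
  vals[!is.finite(vals)] <- NA_real_
  if (!is.null(nodata) && is.finite(nodata)) vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  x_origin <- tiepoint[4]
  y_top <- tiepoint[5]
  raster_grid(m, x_origin, y_top - height * scale[2], scale[1])
}

write_geotiff <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- grid$n_cols
  h <- grid$n_rows
  vals <- as.vector(t(grid$values)) # row-major from the north, TIFF order
  vals[is.na(vals)] <- NaN
  data_offset <- 8L
  data_bytes <- 8L * w * h
  ifd_offset <- data_offset + data_bytes
  nodata_str <- "nan"
  entries <- list(
    list(256L, 4L, 1L, w),
    list(257L, 4L, 1L, h),
    list(258L, 3L, 1L, 64L),
    list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L),
    list(273L, 4L, 1L, data_offset),
    list(277L, 3L, 1L, 1L),
    list(278L, 4L, 1L, h),
    list(279L, 4L, 1L, data_bytes),
    list(339L, 3L, 1L, 3L),
    list(33550L, 12L, 3L, c(grid$cell_size, grid$cell_size, 0)),
    list(33922L, 12L, 6L, c(
      0, 0, 0,
      grid$x_origin, grid$y_origin + h * grid$cell_size, 0
    )),
    list(42113L, 2L, nchar(nodata_str) + 1L, nodata_str)
  )
  n <- length(entries)
  # out-of-line values live directly after the IFD
  overflow_offset <- ifd_offset + 2L + 12L * n + 4L
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(vals, con, size = 8, endian = "little")
  writeBin(n, con, size = 2, endian = "little")
  overflow <- list()
  cursor <- overflow_offset
  for (e in entries) {
    tag <- e[[1]]
    type <- e[[2]]
    count <- e[[3]]
    value <- e[[4]]
    writeBin(tag, con, size = 2, endian = "little")
    writeBin(type, con, size = 2, endian = "little")
    writeBin(count, con, size = 4, endian = "little")
    sz <- tiff_type_size[[as.character(type)]]
    if (sz * count <= 4) {
      pad_con <- rawConnection(raw(0), "w")
      if (type == 2) {
        writeBin(c(charToRaw(value), as.raw(0)), pad_con)
      } else {
        writeBin(as.integer(value), pad_con, size = sz, endian = "little")
      }
      payload <- rawConnectionValue(pad_con)
      close(pad_con)
      writeBin(c(payload, raw(4 - length(payload))), con)
    } else {
      writeBin(cursor, con, size = 4, endian = "little")
      overflow <- c(overflow, list(e))
      cursor <- cursor + sz * count
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  for (e in overflow) {
    type <- e[[2]]
    value <- e[[4]]
    if (type == 2) {
      writeBin(c(charToRaw(value), as.raw(0)), con)
    } else if (type == 12) {
      writeBin(as.double(value), con, size = 8, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = tiff_type_size[[as.character(type)]], endian = "little")
    }
  }
}
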