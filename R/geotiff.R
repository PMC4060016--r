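# Minimal single-band GeoTIFF codec.
#
# No installed package in this stack reads or writes float32 GeoTIFF, so the
# package carries its own small codec: uncompressed, single band, one strip
# on write; on read it accepts multi-strip files, both byte orders, and
# uint8/16/32, int8/16/32, float32/64 sample formats. Georeferencing uses
# ModelPixelScale (33550) + ModelTiepoint (33922); nodata uses the GDAL
# convention (tag 42113), stored as NaN in float payloads. Layer name/units/
# CRS label ride in ImageDescription (270) as a small JSON object.

TIFF_TYPES <- list(
  `1` = list(size = 1, what = "integer", signed = FALSE),  # BYTE
  `2` = list(size = 1, what = "character"),                # ASCII
  `3` = list(size = 2, what = "integer", signed = FALSE),  # SHORT
  `4` = list(size = 4, what = "integer", signed = FALSE),  # LONG
  `6` = list(size = 1, what = "integer", signed = TRUE),   # SBYTE
  `8` = list(size = 2, what = "integer", signed = TRUE),   # SSHORT
  `9` = list(size = 4, what = "integer", signed = TRUE),   # SLONG
  `11` = list(size = 4, what = "double"),                  # FLOAT
  `12` = list(size = 8, what = "double"))                  # DOUBLE

#' Write a raster layer as a single-band float32 GeoTIFF
#'
#' Values are stored uncompressed as IEEE-754 float32, row-major from the
#' north row; nodata cells are stored as NaN and flagged via the GDAL nodata
#' tag. Geometry (cell size, upper-left corner) is stored in the standard
#' ModelPixelScale/ModelTiepoint tags, so files open in ordinary GIS tools.
#' Writing then reading a layer round-trips values (at float32 precision),
#' grid geometry and the nodata mask exactly.
#'
#' @param layer a [si_raster()].
#' @param path output file path.
#' @param expect_grid optional [si_grid()]: if supplied and the layer is not
#'   aligned to it, an alignment error is raised (guards writes into an
#'   existing stack).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, expect_grid = NULL) {
  stopifnot(inherits(layer, "si_raster"))
  if (!is.null(expect_grid)) stop_if_misaligned(layer, expect_grid, "write target grid")
  g <- layer$grid
  desc <- jsonlite::toJSON(list(name = layer$name, units = layer$units,
                                crs_label = g$crs_label), auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  n_entries <- 15L
  ifd_offset <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L
  desc_offset <- ifd_offset + ifd_size
  scale_offset <- desc_offset + length(desc_raw)
  tiepoint_offset <- scale_offset + 24L
  data_offset <- tiepoint_offset + 48L
  n_bytes <- 4L * g$n_rows * g$n_cols

  con <- file(path, "wb")
  on.exit(close(con))
  wU16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wU32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value, inline_short = FALSE) {
    wU16(tag); wU16(type); wU32(count)
    if (inline_short) { wU16(value); wU16(0L) } else wU32(value)
  }
  writeBin(charToRaw("II"), con); wU16(42L); wU32(ifd_offset)
  wU16(n_entries)
  entry(256L, 4L, 1L, g$n_cols)                       # ImageWidth
  entry(257L, 4L, 1L, g$n_rows)                       # ImageLength
  entry(258L, 3L, 1L, 32L, inline_short = TRUE)       # BitsPerSample
  entry(259L, 3L, 1L, 1L, inline_short = TRUE)        # Compression: none
  entry(262L, 3L, 1L, 1L, inline_short = TRUE)        # Photometric: min-is-black
  entry(270L, 2L, length(desc_raw), desc_offset)      # ImageDescription
  entry(273L, 4L, 1L, data_offset)                    # StripOffsets
  entry(277L, 3L, 1L, 1L, inline_short = TRUE)        # SamplesPerPixel
  entry(278L, 4L, 1L, g$n_rows)                       # RowsPerStrip
  entry(279L, 4L, 1L, n_bytes)                        # StripByteCounts
  entry(284L, 3L, 1L, 1L, inline_short = TRUE)        # PlanarConfig
  entry(339L, 3L, 1L, 3L, inline_short = TRUE)        # SampleFormat: IEEE float
  entry(33550L, 12L, 3L, scale_offset)                # ModelPixelScale
  entry(33922L, 12L, 6L, tiepoint_offset)             # ModelTiepoint
  { wU16(42113L); wU16(2L); wU32(4L)                  # GDAL_NODATA "nan"
    writeBin(c(charToRaw("nan"), as.raw(0)), con) }
  wU32(0L)                                            # next IFD: none
  writeBin(desc_raw, con)
  writeBin(c(g$cell_size, g$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, g$origin[1], g$origin[2], 0), con,
           size = 8, endian = "little")
  vals <- as.vector(t(layer$values))
  vals[as.vector(t(layer$nodata_mask))] <- NaN
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-band GeoTIFF as a raster layer
#'
#' Accepts uncompressed single-band TIFFs in either byte order with integer
#' or IEEE-float samples. Multi-band or compressed files are rejected.
#' Nodata cells (GDAL nodata tag, or NaN payload values) populate the layer's
#' nodata mask.
#'
#' @param path file to read.
#' @return a [si_raster()].
#' @export
read_raster <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("unsupported-format error: not a TIFF file")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("unsupported-format error: not a TIFF file"))
  rd <- function(offset, n, size, what = "integer", signed = TRUE) {
    readBin(raw_all[(offset + 1):(offset + n * size)], what, n = n,
            size = size, endian = endian, signed = signed)
  }
  if (rd(2, 1, 2, signed = FALSE) != 42L)
    stop("unsupported-format error: not a TIFF file")
  ifd_offset <- rd(4, 1, 4)
  n_entries <- rd(ifd_offset, 1, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    eo <- ifd_offset + 2 + 12 * (i - 1)
    tag <- rd(eo, 1, 2, signed = FALSE)
    type <- as.character(rd(eo + 2, 1, 2, signed = FALSE))
    count <- rd(eo + 4, 1, 4)
    tt <- TIFF_TYPES[[type]]
    if (is.null(tt)) next
    total <- tt$size * count
    voff <- if (total <= 4) eo + 8 else rd(eo + 8, 1, 4)
    value <- if (tt$what == "character") {
      v <- raw_all[(voff + 1):(voff + count)]
      rawToChar(v[v != as.raw(0)])
    } else if (tt$what == "double") {
      rd(voff, count, tt$size, what = "double")
    } else {
      # unsigned 4-byte ints > 2^31 never occur in files we accept
      rd(voff, count, tt$size, signed = isTRUE(tt$signed) || tt$size == 4)
    }
    tags[[as.character(tag)]] <- value
  }
  need <- function(tag) tags[[as.character(tag)]] %||%
    stop("unsupported-format error: missing TIFF tag ", tag)
  n_cols <- need(256); n_rows <- need(257)
  spp <- tags[["277"]] %||% 1L
  if (spp != 1L)
    stop("unsupported-format error: multi-band TIFF (", spp, " samples/pixel)")
  if ((tags[["259"]] %||% 1L) != 1L)
    stop("unsupported-format error: compressed TIFF")
  bps <- need(258); fmt <- tags[["339"]] %||% 1L
  strip_offsets <- need(273)
  strip_counts <- tags[["279"]] %||% (n_rows * n_cols * bps / 8)
  n_per_strip <- strip_counts / (bps / 8)
  vals <- unlist(lapply(seq_along(strip_offsets), function(i) {
    if (fmt == 3L) {
      if (!bps %in% c(32L, 64L))
        stop("unsupported-format error: float", bps, " samples")
      rd(strip_offsets[i], n_per_strip[i], bps / 8, what = "double")
    } else if (fmt %in% c(1L, 2L)) {
      if (!bps %in% c(8L, 16L, 32L))
        stop("unsupported-format error: ", bps, "-bit integer samples")
      rd(strip_offsets[i], n_per_strip[i], bps / 8,
         signed = fmt == 2L || bps == 32L)
    } else stop("unsupported-format error: sample format ", fmt)
  }))
  if (length(vals) != n_rows * n_cols)
    stop("unsupported-format error: payload size mismatch")
  values <- matrix(vals, n_rows, n_cols, byrow = TRUE)

  scale <- tags[["33550"]]; tie <- tags[["33922"]]
  cell_size <- if (!is.null(scale)) scale[1] else 1
  origin <- if (!is.null(tie)) {
    c(tie[4] - tie[1] * cell_size, tie[5] + tie[2] * cell_size)
  } else c(0, n_rows * cell_size)
  meta <- list(name = basename(path), units = "", crs_label = "unknown")
  if (!is.null(tags[["270"]]) && startsWith(trimws(tags[["270"]]), "{")) {
    parsed <- tryCatch(jsonlite::fromJSON(tags[["270"]]),
                       error = function(e) NULL)
    if (is.list(parsed)) meta <- utils::modifyList(meta, parsed)
  }
  nodata <- !is.finite(values)
  nd_tag <- tags[["42113"]]
  if (!is.null(nd_tag) && !tolower(trimws(nd_tag)) %in% c("nan", "")) {
    ndv <- suppressWarnings(as.numeric(trimws(nd_tag)))
    if (is.finite(ndv)) nodata <- nodata | (values == ndv)
  }
  g <- si_grid(n_rows, n_cols, cell_size = cell_size, origin = origin,
               crs_label = meta$crs_label %||% "unknown")
  si_raster(values, g, nodata_mask = nodata,
            name = meta$name %||% basename(path), units = meta$units %||% "")
}
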