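# File formats: ENVI BIL rasters with wavelength metadata, CSV tables.

envi_header_path <- function(path) paste0(tools::file_path_sans_ext(path), ".hdr")

write_envi_header <- function(path, nx, ny, nb, interleave, fields) {
  lines <- c(
    "ENVI",
    sprintf("samples = %d", nx),
    sprintf("lines = %d", ny),
    sprintf("bands = %d", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0"
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) > 1) {
      lines <- c(lines, sprintf("%s = {%s}", nm,
                                paste(format(v, digits = 10), collapse = ", ")))
    } else {
      lines <- c(lines, sprintf("%s = %s", nm, as.character(v)))
    }
  }
  writeLines(lines, envi_header_path(path))
}

parse_envi_header <- function(hdr_path) {
  raw <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  # split on newlines not inside braces so multi-line lists stay together
  chars <- strsplit(raw, "")[[1]]
  depth <- 0; cur <- ""; lines <- character()
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1
    if (ch == "}") depth <- depth - 1
    if (ch == "\n" && depth == 0) { lines <- c(lines, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  lines <- c(lines, cur)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}\n]", "", val)
      out[[key]] <- as.numeric(trimws(strsplit(val, ",")[[1]]))
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Write a spectral cube as an ENVI BIL raster
#'
#' Float32 band-interleaved-by-line binary with a text header carrying the
#' wavelength list (nm), pixel size and the units tag. Lossless for float32
#' payloads.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; the data file is written at `path` and the
#'   header next to it with extension `.hdr`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$values)
  write_envi_header(path, d[2], d[1], d[3], "bil",
                    list(`wavelength units` = "Nanometers",
                         wavelength = cube$wavelengths,
                         `pixel size` = c(cube$gsd, cube$gsd),
                         `map origin` = c(cube$x0, cube$y0),
                         units = cube$units))
  con <- file(path, "wb")
  on.exit(close(con))
  # BIL: for each line, all bands' samples; line 1 = southernmost row
  v <- aperm(cube$values, c(2, 3, 1))  # [col, band, row]
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an ENVI BIL spectral cube
#'
#' @param path path to the binary data file (header expected at the same
#'   basename with extension `.hdr`). The header must carry a wavelength
#'   list and a units tag.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) {
    stop(sprintf("ENVI header '%s' not found", hdr_path), call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength)) {
    stop("ENVI header has no wavelength list", call. = FALSE)
  }
  if (is.null(h$units)) stop("ENVI header has no units tag", call. = FALSE)
  nx <- as.integer(h$samples); ny <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = nx * ny * nb, size = 4, endian = "little")
  dim(v) <- c(nx, nb, ny)
  ps <- if (!is.null(h$`pixel size`)) h$`pixel size`[1] else 1
  orig <- h$`map origin` %||% c(0, 0)
  spectral_cube(aperm(v, c(3, 1, 2)), h$wavelength, ps, orig[1], orig[2],
                units = h$units)
}

#' Write a single-band raster as ENVI float32
#'
#' @param layer a [raster_layer()].
#' @param path output binary path (header written alongside).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  fields <- list(`pixel size` = c(layer$gsd, layer$gsd),
                 `map origin` = c(layer$x0, layer$y0),
                 units = layer$units, `band names` = layer$name)
  if (!is.null(layer$wavelengths_nm)) {
    fields$wavelength <- layer$wavelengths_nm
    fields$`wavelength units` <- "Nanometers"
  }
  write_envi_header(path, ncol(layer$values), nrow(layer$values), 1L,
                    "bsq", fields)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(layer$values)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-band ENVI raster
#'
#' @param path binary data path with `.hdr` header alongside.
#' @return A [raster_layer()].
#' @export
read_raster <- function(path) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) {
    stop(sprintf("ENVI header '%s' not found", hdr_path), call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  if (is.null(h$units)) stop("ENVI header has no units tag", call. = FALSE)
  nx <- as.integer(h$samples); ny <- as.integer(h$lines)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = nx * ny, size = 4, endian = "little")
  ps <- if (!is.null(h$`pixel size`)) h$`pixel size`[1] else 1
  orig <- h$`map origin` %||% c(0, 0)
  raster_layer(matrix(v, ny, nx, byrow = TRUE), ps, orig[1], orig[2],
               units = h$units, name = h$`band names` %||% "layer",
               wavelengths_nm = h$wavelength)
}

#' Read a CSV table with format validation
#'
#' UTF-8 CSV with a header row and "." decimals. Fields that look like
#' comma-decimal numbers (e.g. `3,14`) raise a format error naming the first
#' offending row.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (col in names(df)) {
    if (is.character(df[[col]])) {
      bad <- grepl("^-?[0-9]+,[0-9]+$", df[[col]])
      if (any(bad)) {
        stop(sprintf("comma decimal in column '%s', row %d: use '.' decimals",
                     col, which(bad)[1]), call. = FALSE)
      }
    }
  }
  df
}

#' Write a data frame as CSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  drop <- vapply(df, is.list, logical(1))
  utils::write.csv(df[, !drop, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
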