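# ENVI cube I/O: band-sequential (BSQ) raw binary plus a plain-text .hdr
# header carrying the wavenumber list and the cube's provenance fields.

#' Write a cube to an ENVI file pair
#'
#' Writes `path` (raw BSQ binary) and `paste0(path, ".hdr")`. Data type 4
#' (32-bit float, the interchange default) or 5 (64-bit double, lossless).
#' The header carries the wavenumber list plus `ftirsim stage` / `ftirsim
#' seed` fields so [read_cube()] restores the metadata.
#'
#' @param cube an [ftir_cube()].
#' @param path output data file path (header written alongside).
#' @param format `"envi"` (the only supported container).
#' @param precision `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = "envi",
                       precision = c("float32", "float64")) {
  format <- match.arg(format)
  precision <- match.arg(precision)
  d <- cube_dims(cube)
  size <- if (precision == "float32") 4L else 8L
  hdr <- c(
    "ENVI",
    "description = {ftirsim hyperspectral cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", if (size == 4L) 4L else 5L),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Wavenumber",
    paste0("wavelength = {", paste(format(as.numeric(cube$axis), trim = TRUE,
                                          digits = 15), collapse = ", "), "}"),
    paste0("ftirsim stage = ", cube$meta$stage %||% "clean"))
  if (!is.null(cube$meta$seed)) hdr <- c(hdr, paste0("ftirsim seed = ", cube$meta$seed))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: samples (columns) fastest, then lines, then bands
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con, size = size,
           endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # simple "key = value" lines (brace-delimited values fixed up below)
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[tolower(key)]] <- val
  }
  # multi-line brace values
  m <- regmatches(txt, gregexpr("[a-zA-Z ]+=[ ]*\\{[^}]*\\}", txt))[[1]]
  for (blk in m) {
    key <- tolower(trimws(sub("=.*", "", blk)))
    val <- sub("^[^{]*\\{", "", blk)
    val <- trimws(sub("\\}\\s*$", "", val))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI cube written by [write_cube()] or compatible tools
#'
#' Supports BSQ interleave with data types 4 (float32) and 5 (float64).
#'
#' @param path data file path; the header is looked up at `paste0(path,
#'   ".hdr")` (or `path` with its extension replaced by `.hdr`).
#' @return An [ftir_cube()]; stage and seed are restored when present.
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path))
    stop("no ENVI header found for '", path, "'", call. = FALSE)
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  h <- parse_envi_header(hdr_path)
  for (key in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(h[[key]]))
      stop("ENVI header is missing the '", key, "' field", call. = FALSE)
  if (tolower(h[["interleave"]]) != "bsq")
    stop("only BSQ interleave is supported (got '", h[["interleave"]], "')",
         call. = FALSE)
  dt <- as.integer(h[["data type"]])
  if (!dt %in% c(4L, 5L))
    stop("unsupported ENVI data type ", dt, " (need 4 or 5)", call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("ENVI header is missing the 'wavelength' dataset", call. = FALSE)
  samples <- as.integer(h[["samples"]])
  lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  wn <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wn) != bands)
    stop("wavelength list length (", length(wn), ") does not match bands (",
         bands, ")", call. = FALSE)
  n <- samples * lines * bands
  size <- if (dt == 4L) 4L else 8L
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = size, endian = "little")
  if (length(vals) != n)
    stop("truncated ENVI data file: expected ", n, " values, got ",
         length(vals), call. = FALSE)
  data <- aperm(array(vals, c(samples, lines, bands)), c(2, 1, 3))
  seed <- if (!is.null(h[["ftirsim seed"]])) as.integer(h[["ftirsim seed"]])
  ftir_cube(data, as_spectral_axis(wn), stage = h[["ftirsim stage"]] %||% "clean",
            meta = list(seed = seed))
}
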