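#' Read a hypercube from disk
#'
#' Reads the ENVI-style dialect written by [write_cube()]: a plain-text
#' `.hdr` file of `key = value` pairs next to a raw little-endian binary
#' payload, band-interleaved-by-line (BIL: for each scan line, for each
#' spectral band, all slit samples). The header keys `samples` (slit),
#' `lines` (scan) and `bands` (spectral) must agree with the payload size.
#'
#' @param path Path to the binary payload; the header is `<path>.hdr`.
#' @param dialect Storage dialect. Only `"envi"` is supported.
#' @return A [hypercube()]; the wavelength axis is restored when present in
#'   the header, and a companion `<path>.mask` file, if any, is restored into
#'   the cube's `mask` element.
#' @export
read_cube <- function(path, dialect = c("envi", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the hdf5 dialect is not supported by this build; use \"envi\"",
         call. = FALSE)
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header file: ", hdr_path, call. = FALSE)
  if (!file.exists(path)) stop("missing binary payload: ", path, call. = FALSE)
  hdr <- parse_envi_header(hdr_path)
  for (key in c("samples", "lines", "bands"))
    if (is.null(hdr[[key]]))
      stop(sprintf("malformed header: missing key '%s'", key), call. = FALSE)
  n_slit <- as.integer(hdr$samples)
  n_scan <- as.integer(hdr$lines)
  n_spec <- as.integer(hdr$bands)
  if (!is.null(hdr$interleave) && tolower(hdr$interleave) != "bil")
    stop(sprintf("malformed header: unsupported interleave '%s'", hdr$interleave),
         call. = FALSE)
  n <- n_slit * n_scan * n_spec
  payload_bytes <- file.size(path)
  if (payload_bytes != n * 8)
    stop(sprintf("size error: header declares %d x %d x %d (%d bytes), payload has %d bytes",
                 n_scan, n_slit, n_spec, n * 8L, payload_bytes), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  # BIL: samples fastest, then bands, then lines -> array (slit, spectral, scan)
  v <- array(v, dim = c(n_slit, n_spec, n_scan))
  values <- aperm(v, c(3, 1, 2))
  wl <- hdr$wavelength
  meta <- hdr$meta %||% list()
  cube <- hypercube(values, wavelength = wl, meta = meta)
  mask_path <- paste0(path, ".mask")
  if (file.exists(mask_path)) {
    mcon <- file(mask_path, "rb")
    m <- readBin(mcon, "integer", n = n, size = 1L, signed = FALSE)
    close(mcon)
    m <- array(as.logical(m), dim = c(n_slit, n_spec, n_scan))
    cube$mask <- aperm(m, c(3, 1, 2))
  }
  cube
}

#' Write a hypercube to disk
#'
#' Writes the ENVI-style pair described in [read_cube()]: `<path>.hdr` text
#' header and raw BIL little-endian doubles at `path`. A wavelength axis is
#' written only when present (never as zeros); a cube `mask` element is
#' written as a companion byte-per-pixel `<path>.mask` file.
#'
#' @param cube A [hypercube()].
#' @param path Output path for the binary payload.
#' @param dialect Storage dialect. Only `"envi"` is supported.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5")
    stop("the hdf5 dialect is not supported by this build; use \"envi\"",
         call. = FALSE)
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube)
  lines <- c(
    "ENVI",
    "dialect = envi",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "interleave = bil",
    "data type = 5",
    "byte order = 0"
  )
  if (!is.null(cube$wavelength))
    lines <- c(lines, paste0("wavelength = {",
                             paste(format(cube$wavelength, digits = 17),
                                   collapse = ", "), "}"))
  if (length(cube$meta)) {
    kv <- vapply(names(cube$meta), function(k)
      sprintf("meta %s = %s", k, format(cube$meta[[k]], digits = 17)), "")
    lines <- c(lines, kv)
  }
  tryCatch({
    writeLines(lines, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    v <- aperm(cube$values, c(2, 3, 1))  # (slit, spectral, scan): BIL order
    writeBin(as.double(v), con, size = 8L, endian = "little")
  }, error = function(e)
    stop("I/O error writing cube to ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(cube$mask)) {
    mcon <- file(paste0(path, ".mask"), "wb")
    writeBin(as.integer(aperm(cube$mask, c(2, 3, 1))), mcon, size = 1L)
    close(mcon)
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  out <- list(meta = list())
  buf <- ""
  in_brace <- FALSE
  for (line in txt) {
    if (in_brace) { buf <- paste(buf, line); in_brace <- !grepl("\\}", line); if (in_brace) next; line <- buf }
    else if (grepl("\\{", line) && !grepl("\\}", line)) { buf <- line; in_brace <- TRUE; next }
    if (!grepl("=", line)) next
    key <- trimws(sub("=.*", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- as.numeric(trimws(strsplit(val, ",")[[1]]))
    }
    if (grepl("^meta ", key)) {
      mk <- sub("^meta ", "", key)
      num <- suppressWarnings(as.numeric(val))
      out$meta[[mk]] <- if (!is.na(num)) num else val
    } else out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
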