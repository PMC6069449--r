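#' Read and write ENVI-style hyperspectral cubes
#'
#' Cubes are persisted as a plain-text `.hdr` header plus a raw
#' little-endian 32-bit float binary in band-interleaved-by-line (BIL) or
#' band-sequential (BSQ) layout. The header records `samples`, `lines`,
#' `bands`, `data type`, `interleave`, `byte order`, the wavelength list,
#' `map info`, and two package keys (`affine geo transform`, `cube kind`);
#' unknown keys are preserved verbatim on round trip. BIP interleave and
#' non-float data types are not supported.
#'
#' @param cube A `spectral_cube` with finite values.
#' @param path Path of the binary file; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bil"` or `"bsq"`.
#' @return `write_cube` invisibly returns `path`; `read_cube` returns the
#'   `spectral_cube`.
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bsq")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  if (!all(is.finite(cube$values))) {
    stop("cube contains non-finite values", call. = FALSE)
  }
  d <- dim(cube$values)
  extra <- attr(cube, "envi_extra_keys")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelength, digits = 12, trim = TRUE),
                  collapse = ", "))
  )
  if (!is.null(cube$gt)) {
    gtv <- c(cube$gt$origin, as.numeric(t(cube$gt$A)))
    hdr <- c(hdr, sprintf("affine geo transform = { %s }",
                          paste(format(gtv, digits = 15, trim = TRUE),
                                collapse = ", ")))
  }
  if (!is.null(extra)) hdr <- c(hdr, extra)
  writeLines(hdr, paste0(path, ".hdr"))

  # file order: BIL = line-major (band, sample within line);
  # BSQ = band-major (line, sample within band)
  v <- cube$values
  out <- switch(interleave,
    bil = aperm(v, c(2, 3, 1)),  # sample fastest, then band, then line
    bsq = aperm(v, c(2, 1, 3))   # sample fastest, then line, then band
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(out), con, size = 4L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || trimws(lines[1]) != "ENVI") {
    stop("not an ENVI header: ", hdr_path, call. = FALSE)
  }
  # join multi-line { ... } values
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in lines[-1]) {
    buf <- if (open) paste(buf, ln) else ln
    nopen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nclose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    open <- nopen > nclose
    if (!open) {
      joined <- c(joined, buf)
      buf <- ""
    }
  }
  kv <- regmatches(joined, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", joined))
  keys <- vapply(kv, function(m) if (length(m) == 3) tolower(m[2]) else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  ok <- !is.na(keys)
  stats::setNames(as.list(vals[ok]), keys[ok])
}

envi_num_list <- function(s) {
  s <- gsub("[{}]", "", s)
  as.numeric(trimws(strsplit(s, ",")[[1]]))
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header: ", hdr_path, call. = FALSE)
  if (!file.exists(path)) stop("missing binary: ", path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop("header missing required keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  if (as.integer(h[["data type"]]) != 4L) {
    stop("unsupported ENVI data type (only 4 = float32)", call. = FALSE)
  }
  interleave <- tolower(trimws(h$interleave))
  if (!interleave %in% c("bil", "bsq")) {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  n <- samples * lines * bands
  sz <- file.info(path)$size
  if (is.na(sz) || sz != n * 4) {
    stop(sprintf("corrupt cube: binary is %s bytes, header implies %d",
                 format(sz), n * 4), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  values <- switch(interleave,
    bil = aperm(array(raw, c(samples, bands, lines)), c(3, 1, 2)),
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3))
  )
  wl <- if (!is.null(h$wavelength)) envi_num_list(h$wavelength) else
    seq_len(bands)
  if (length(wl) != bands) {
    stop("header wavelength list length does not match band count",
         call. = FALSE)
  }
  gt <- NULL
  if (!is.null(h[["affine geo transform"]])) {
    g <- envi_num_list(h[["affine geo transform"]])
    gt <- geo_transform(g[1:2], matrix(g[3:6], 2, 2, byrow = TRUE))
  }
  kind <- if (!is.null(h[["cube kind"]])) trimws(h[["cube kind"]]) else
    "radiance"
  known <- c(need, "header offset", "file type", "byte order", "cube kind",
             "wavelength", "wavelength units", "affine geo transform")
  extra <- joined_unknown_keys(h, known)
  cube <- spectral_cube(values, wl, gt, kind)
  if (length(extra)) attr(cube, "envi_extra_keys") <- extra
  cube
}

joined_unknown_keys <- function(h, known) {
  nm <- setdiff(names(h), known)
  if (!length(nm)) return(character(0))
  vapply(nm, function(k) sprintf("%s = %s", k, h[[k]]), character(1),
         USE.NAMES = FALSE)
}

#' Write/read a single-band raster as an ENVI file
#'
#' Used for depth maps, index rasters, class-id maps, and masks. Values are
#' stored as float32; an optional plain-text lookup sidecar
#' (`<path>.classes.txt`, one `id,name` per line) carries class legends.
#'
#' @param m Numeric or integer matrix.
#' @param path Output path (header at `<path>.hdr`).
#' @param gt Optional `geo_transform`.
#' @param legend Optional character vector of class names for integer
#'   rasters; written to the lookup sidecar.
#' @export
write_band_raster <- function(m, path, gt = NULL, legend = NULL) {
  cube <- spectral_cube(array(m, c(dim(m), 1L)), 1, gt, "radiance")
  write_cube(cube, path, "bsq")
  if (!is.null(legend)) {
    writeLines(sprintf("%d,%s", seq_along(legend), legend),
               paste0(path, ".classes.txt"))
  }
  invisible(path)
}

#' @rdname write_band_raster
#' @export
read_band_raster <- function(path) {
  cube <- read_cube(path)
  m <- cube$values[, , 1]
  lk <- paste0(path, ".classes.txt")
  if (file.exists(lk)) {
    rows <- strsplit(readLines(lk, warn = FALSE), ",")
    legend <- vapply(rows, `[`, character(1), 2)
    attr(m, "legend") <- legend
  }
  attr(m, "gt") <- cube$gt
  m
}
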