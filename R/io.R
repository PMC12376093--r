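## File dialect (deliberately narrow, with strict errors):
##   1D: two numeric columns (wavenumber cm-1, value), whitespace- or
##       comma-delimited, '#' starts a comment line. A row with only a
##       wavenumber (empty value field) is a masked point.
##   2D: axis-bordered matrix; cell (1,1) empty or "pump\probe"; first row
##       = probe axis; first column = pump axis; body = delta-OD.

.splitFields <- function(line) {
  line <- sub("#.*$", "", line)
  line <- gsub(",", " ", line)
  strsplit(trimws(line), "[[:space:]]+")[[1L]]
}

.parseNum <- function(tok, path, i, what = "field") {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v))
    tdsStop("tds_parse_error",
            sprintf("%s: line %d: non-numeric %s '%s'", path, i, what,
                    tok[which(is.na(v))[1L]]))
  v
}

#' Read a 1D spectrum from delimited text
#'
#' Reads the two-column dialect (wavenumber cm^-1, value; whitespace or
#' comma delimited; \code{#} comments; an empty value field marks a masked
#' point). Rows are sorted by ascending wavenumber; duplicate wavenumbers
#' are rejected.
#'
#' @param path file path.
#' @param role role tag recorded on the spectrum (see [Spectrum1D-class]).
#' @return a [Spectrum1D-class].
#' @seealso [writeSpectrum1D()]
#' @export
readSpectrum1D <- function(path, role = "generic") {
  if (!file.exists(path))
    tdsStop("tds_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  axis <- numeric(); vals <- numeric(); mask <- logical()
  for (i in seq_along(lines)) {
    raw <- lines[i]
    ## masked row: a wavenumber followed by an empty (comma- or tab-marked)
    ## value field, before comment stripping of the delimiter itself
    tok <- .splitFields(raw)
    if (length(tok) == 0L) next
    if (length(tok) == 1L) {
      body <- sub("#.*$", "", raw)
      if (!grepl("[,\t]", body))
        tdsStop("tds_parse_error",
                sprintf("%s: line %d: expected two columns, got 1", path, i))
      axis <- c(axis, .parseNum(tok, path, i, "wavenumber"))
      vals <- c(vals, NA_real_); mask <- c(mask, FALSE)
      next
    }
    if (length(tok) != 2L)
      tdsStop("tds_parse_error",
              sprintf("%s: line %d: expected two columns, got %d",
                      path, i, length(tok)))
    v <- .parseNum(tok, path, i)
    axis <- c(axis, v[1L]); vals <- c(vals, v[2L]); mask <- c(mask, TRUE)
  }
  if (length(axis) < 3L)
    tdsStop("tds_size_error",
            sprintf("%s: spectrum needs at least 3 points, got %d",
                    path, length(axis)))
  spectrum1d(axis, vals, role = role, mask = mask,
             meta = list(source = path))
}

#' Write a 1D spectrum to delimited text
#'
#' Two-column text with a \code{#} header recording the role and metadata;
#' values are written with 10 significant digits so that a read/write
#' round-trip is lossless to better than 1e-9 relative error. Masked points
#' are written as rows with an empty value field.
#'
#' @param spec a [Spectrum1D-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readSpectrum1D()]
#' @export
writeSpectrum1D <- function(spec, path) {
  hdr <- c(sprintf("# role: %s", spec@role),
           sprintf("# columns: wavenumber_cm-1%svalue", "\t"))
  for (nm in names(spec@meta)) {
    v <- spec@meta[[nm]]
    if (is.atomic(v) && length(v) == 1L)
      hdr <- c(hdr, sprintf("# meta %s: %s", nm, format(v)))
  }
  if (any(!spec@mask))
    hdr <- c(hdr, "# masked points appear as rows with an empty value field")
  rows <- ifelse(spec@mask,
                 sprintf("%.10g\t%.10g", spec@axis, spec@values),
                 sprintf("%.10g\t", spec@axis))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tdsStop("tds_io_error", sprintf("cannot write to: %s", path))
  invisible(path)
}

#' Read a 2D IR spectrum from an axis-bordered matrix file
#'
#' First row: probe axis (cell (1,1) empty or the literal
#' \code{pump\\probe}); first column: pump axis; body: the \eqn{\Delta}OD
#' matrix. Axes are sorted ascending with rows/columns permuted to match.
#'
#' @param path file path.
#' @return a [Spectrum2D-class].
#' @seealso [writeSpectrum2D()]
#' @export
readSpectrum2D <- function(path) {
  if (!file.exists(path))
    tdsStop("tds_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    tdsStop("tds_size_error", sprintf("%s: matrix needs >= 2 pump rows", path))
  first <- .splitFields(sub("^[[:space:]]*pump\\\\probe", "", lines[1L]))
  probe <- .parseNum(first, path, 1L, "probe-axis value")
  np <- length(probe)
  pump <- numeric(length(lines) - 1L)
  M <- matrix(NA_real_, length(lines) - 1L, np)
  for (r in seq_len(length(lines) - 1L)) {
    tok <- .splitFields(lines[r + 1L])
    if (length(tok) != np + 1L)
      tdsStop("tds_parse_error",
              sprintf("%s: line %d: ragged row (expected %d fields, got %d)",
                      path, r + 1L, np + 1L, length(tok)))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      tdsStop("tds_parse_error",
              sprintf("%s: line %d, field %d: non-numeric cell '%s'",
                      path, r + 1L, j, tok[j]))
    }
    pump[r] <- v[1L]; M[r, ] <- v[-1L]
  }
  spectrum2d(pump, probe, M, meta = list(source = path))
}

#' Write a 2D IR spectrum to an axis-bordered matrix file
#'
#' @param spec2d a [Spectrum2D-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readSpectrum2D()]
#' @export
writeSpectrum2D <- function(spec2d, path) {
  hdr <- paste(c("pump\\probe", sprintf("%.10g", spec2d@probeAxis)),
               collapse = "\t")
  rows <- vapply(seq_along(spec2d@pumpAxis), function(r)
    paste(c(sprintf("%.10g", spec2d@pumpAxis[r]),
            sprintf("%.10g", spec2d@signal[r, ])), collapse = "\t"),
    character(1))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tdsStop("tds_io_error", sprintf("cannot write to: %s", path))
  invisible(path)
}
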