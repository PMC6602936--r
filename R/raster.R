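#' Single-band raster grid
#'
#' Minimal in-memory container for a single-band landscape raster: a numeric
#' matrix plus cell size and lower-left origin, matching the Arc/Info ASCII
#' grid model. Cells equal to the nodata sentinel are stored as `NA`
#' internally and written back as the sentinel.
#'
#' @param values numeric matrix, row 1 = northernmost row (as in the ASCII
#'   grid format); `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (must be > 0).
#' @param xll,yll x/y coordinate of the lower-left corner of the grid.
#' @param nodata sentinel value used on disk for missing cells.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1000, xll = 0, yll = 0,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell_size = %g, origin = (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

grid_header_string <- function(r) {
  sprintf("ncols %d nrows %d xllcorner %.17g yllcorner %.17g cellsize %.17g",
          ncol(r$values), nrow(r$values), r$xll, r$yll, r$cell_size)
}

#' Read an Arc/Info ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format: a header of
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize` and an optional
#' `NODATA_value`, followed by `nrows` whitespace-separated rows of values
#' (north to south).
#'
#' @param path file path.
#' @return A [raster_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed header at line %d: '%s'", i, lines[i]))
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop(sprintf("non-numeric header value at line %d: '%s'", i, lines[i]))
    hdr[[tolower(parts[1])]] <- val
    i <- i + 1L
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]])) stop(sprintf("header is missing '%s'", req))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  if (length(body) != nrows)
    stop(sprintf("expected %d data rows, found %d (starting at line %d)",
                 nrows, length(body), i))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    toks <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(toks) != ncols)
      stop(sprintf("line %d: expected %d values, found %d",
                   i + r - 1L, ncols, length(toks)))
    row <- suppressWarnings(as.numeric(toks))
    if (anyNA(row))
      stop(sprintf("line %d: non-numeric cell '%s'",
                   i + r - 1L, toks[which(is.na(row))[1]]))
    vals[r, ] <- row
  }
  raster_grid(vals,
              cell_size = hdr$cellsize,
              xll = if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0,
              yll = if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0,
              nodata = nodata)
}

#' Write an Arc/Info ASCII grid
#'
#' Inverse of [read_ascii_grid()]; finite values survive a write/read
#' round trip bit-exactly (17 significant digits). Header lines are emitted
#' in the canonical order `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`.
#'
#' @param r a [raster_grid].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$xll),
    sprintf("yllcorner %.17g", r$yll),
    sprintf("cellsize %.17g", r$cell_size),
    sprintf("NODATA_value %.17g", r$nodata)
  ), con)
  writeLines(apply(v, 1L, function(row) paste(sprintf("%.17g", row),
                                              collapse = " ")), con)
  invisible(path)
}

cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  list(x = r$xll + (seq_len(nc) - 0.5) * cs,
       y = r$yll + (nr - seq_len(nr) + 0.5) * cs)  # row 1 is northernmost
}

#' Locate the cell containing a point
#'
#' @param r a [raster_grid].
#' @param x,y point coordinates (vectors of equal length).
#' @return data.frame with `row`, `col` (1-based matrix indices; row 1 is the
#'   northern edge). Points outside the grid yield `NA`.
#' @export
cell_of <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  col <- floor((x - r$xll) / cs) + 1L
  row <- nr - floor((y - r$yll) / cs)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
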