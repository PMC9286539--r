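#' Lightweight georeferenced grid
#'
#' `pva_raster` is the raster currency of the package: a numeric matrix of
#' per-cell values plus complete grid metadata (square cell size in km and
#' the projected coordinate of the grid's lower-left corner). Row 1 is the
#' southernmost row; column 1 the westernmost column. Coordinates are
#' projected kilometres; at landscape scale no great-circle correction is
#' applied.
#'
#' @param values numeric matrix (rows x cols); `NA` marks missing cells.
#' @param cell_size_km positive cell edge length in km.
#' @param origin numeric length-2 `(x, y)` of the lower-left grid corner, km.
#' @param label optional character tag (e.g. a timestamp such as "2030s").
#' @return an object of class `pva_raster`.
#' @export
pva_raster <- function(values, cell_size_km = 1, origin = c(0, 0), label = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("pva_raster(): values must be numeric")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 || cell_size_km <= 0)
    stop("pva_raster(): cell_size_km must be a single positive number")
  if (length(origin) != 2) stop("pva_raster(): origin must be length 2 (x, y)")
  structure(
    list(values = unname(values), cell_size_km = as.numeric(cell_size_km),
         origin = as.numeric(origin), label = label),
    class = "pva_raster")
}

#' @export
print.pva_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pva_raster> %d x %d cells of %g km%s\n", d[1], d[2],
              x$cell_size_km,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.pva_raster <- function(x) dim(x$values)

#' Test whether two rasters share the same grid
#' @param a,b `pva_raster` objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size_km, b$cell_size_km)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_unless_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop(sprintf("grid mismatch: %s must share dimensions, cell size and origin", what))
  invisible(TRUE)
}

#' Cell-center coordinates of a raster
#'
#' @param x a `pva_raster`.
#' @return data.frame with `row`, `col`, `x`, `y` (km) for every cell in
#'   column-major order.
#' @export
cell_centers <- function(x) {
  d <- dim(x$values)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  data.frame(
    row = rows, col = cols,
    x = x$origin[1] + (cols - 0.5) * x$cell_size_km,
    y = x$origin[2] + (rows - 0.5) * x$cell_size_km)
}

#' Aggregate a raster to a coarser grid by block mean
#'
#' @param x a `pva_raster` whose dimensions are divisible by `factor`.
#' @param factor integer aggregation factor (>= 1).
#' @param fun summary function applied per block (default mean).
#' @return a `pva_raster` with `factor`-times larger cells.
#' @export
aggregate_raster <- function(x, factor, fun = mean) {
  factor <- as.integer(factor)
  if (factor < 1) stop("aggregate_raster(): factor must be >= 1")
  if (factor == 1L) return(x)
  d <- dim(x$values)
  if (any(d %% factor != 0))
    stop("aggregate_raster(): grid dimensions must be divisible by factor")
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- x$values[((i - 1) * factor + 1):(i * factor),
                      ((j - 1) * factor + 1):(j * factor)]
    out[i, j] <- fun(block)
  }
  pva_raster(out, cell_size_km = x$cell_size_km * factor, origin = x$origin,
             label = x$label)
}

#' Replicate a coarse raster onto a nested fine grid
#'
#' Each fine cell takes the value of its containing coarse cell (nearest
#' coarse cell / block replication). The coarse grid must be an integer
#' aggregation of the fine grid.
#'
#' @param coarse a `pva_raster`.
#' @param fine_template a `pva_raster` supplying the target grid.
#' @return a `pva_raster` on the fine grid.
#' @export
disaggregate_raster <- function(coarse, fine_template) {
  df <- dim(fine_template$values); dc <- dim(coarse$values)
  if (any(df %% dc != 0))
    stop("disaggregate_raster(): coarse grid is not an integer aggregation of the fine grid")
  fac <- unique(df %/% dc)
  if (length(fac) != 1)
    stop("disaggregate_raster(): row and column aggregation factors differ")
  vals <- coarse$values[rep(seq_len(dc[1]), each = fac),
                        rep(seq_len(dc[2]), each = fac), drop = FALSE]
  pva_raster(vals, cell_size_km = fine_template$cell_size_km,
             origin = fine_template$origin, label = coarse$label)
}

#' Write a raster to a plain-text grid file
#'
#' The package's native grid format: a two-line header (format tag; then
#' rows, cols, cell size, origin, label) followed by one line per row of
#' `%.17g`-formatted values, which round-trips IEEE doubles bit-identically.
#'
#' @param x a `pva_raster`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_pva_raster <- function(x, path) {
  d <- dim(x$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pva_raster v1", con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g %s", d[1], d[2], x$cell_size_km,
                     x$origin[1], x$origin[2],
                     if (is.null(x$label)) "-" else x$label), con)
  for (i in seq_len(d[1]))
    writeLines(paste(sprintf("%.17g", x$values[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a raster written by [write_pva_raster()]
#'
#' @param path file path.
#' @return a `pva_raster`.
#' @export
read_pva_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || lines[1] != "# pva_raster v1")
    stop("read_pva_raster(): not a pva_raster v1 file: ", path)
  hdr <- strsplit(lines[2], " ", fixed = TRUE)[[1]]
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    tok <- strsplit(lines[2 + i], " ", fixed = TRUE)[[1]]
    # "NA" tokens mark missing cells
    vals[i, ] <- suppressWarnings(as.numeric(tok))
  }
  label <- if (hdr[6] == "-") NULL else hdr[6]
  pva_raster(vals, cell_size_km = as.numeric(hdr[3]),
             origin = as.numeric(hdr[4:5]), label = label)
}
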