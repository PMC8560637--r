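#' Define the analysis grid
#'
#' The analysis grid is a rectangular lattice of square cells in an
#' equal-area frame.  Cells are identified by 0-based row-major ids; row 0 is
#' the *top* (northernmost) row, matching raster conventions.
#'
#' @param rows,cols Lattice dimensions.
#' @param cell_size Cell edge length in projection units (nominally 100 km).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(rows, cols, cell_size = 100, xll = 0, yll = 0) {
  stopifnot(rows >= 1, cols >= 1, cell_size > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, xll = xll, yll = yll),
            class = "grid_spec")
}

n_cells <- function(grid) grid$rows * grid$cols

#' Grid layers: per-cell values of one variable
#'
#' A `grid_layer` stores one value per cell of a [grid_spec()] (NA = masked),
#' together with the variable name and units.
#'
#' @param values Numeric vector of length `rows * cols` in 0-based row-major
#'   cell order (NA for masked cells).
#' @param grid A [grid_spec()].
#' @param name Variable name.
#' @param units Units string (`"m"`, `"degC"`, ...).
#' @return A `grid_layer` object.
#' @export
grid_layer <- function(values, grid, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"), length(values) == n_cells(grid))
  if (any(is.infinite(values))) stop("non-finite unmasked values in layer ", name)
  structure(list(values = as.numeric(values), grid = grid,
                 name = name, units = units), class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("grid_layer '%s' [%s]: %d x %d cells, %d masked\n", x$name,
              x$units, x$grid$rows, x$grid$cols, sum(is.na(x$values))))
  invisible(x)
}

layer_matrix <- function(layer) {
  matrix(layer$values, nrow = layer$grid$rows, ncol = layer$grid$cols,
         byrow = TRUE)
}

#' Read and write ESRI ASCII grids
#'
#' Minimal reader/writer for the ESRI ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header followed by
#' rows of values, northernmost row first).  NODATA pixels become `NA`.
#'
#' @param path File path.
#' @param x For writing: a `grid_layer` or a raster list as returned by
#'   `read_ascii_grid`.
#' @param nodata NODATA sentinel written for `NA` values.
#' @return `read_ascii_grid` returns a list with elements `data` (numeric
#'   matrix, row 1 = northernmost), `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[req]])) stop("missing header field '", req, "' in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d values, found %d in %s",
                 hdr$ncols * hdr$nrows, length(vals), path))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(data = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value %||% -9999)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  if (inherits(x, "grid_layer")) {
    x <- list(data = layer_matrix(x), xll = x$grid$xll, yll = x$grid$yll,
              cellsize = x$grid$cell_size)
  }
  m <- x$data
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", format(x$xll, digits = 15)),
               paste("yllcorner", format(x$yll, digits = 15)),
               paste("cellsize", format(x$cellsize, digits = 15)),
               paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " ")), con)
  invisible(path)
}
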