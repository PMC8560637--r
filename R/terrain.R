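#' Aggregate a raster to the analysis grid by cell means
#'
#' Each grid cell's value is the arithmetic mean of the raster pixels whose
#' *centres* fall inside the cell (half-open intervals `[x0, x1)` so every
#' pixel centre belongs to exactly one cell); NODATA pixels (NA, e.g. masked
#' sea) are excluded, and cells containing no valid pixel centre are masked.
#' The raster must already be in the grid's equal-area frame with resolution
#' at most the cell size.
#'
#' @param raster A raster list as from [read_ascii_grid()] (`data` matrix
#'   with row 1 northernmost, `xll`, `yll`, `cellsize`).
#' @param grid A [grid_spec()].
#' @param name,units Metadata for the output layer.
#' @return A [grid_layer()] of per-cell means.
#' @export
aggregate_raster <- function(raster, grid, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (raster$cellsize > grid$cell_size + 1e-9)
    stop("raster resolution (", raster$cellsize,
         ") coarser than grid cell size (", grid$cell_size, ")")
  nr <- nrow(raster$data); ncp <- ncol(raster$data)
  ## pixel-centre coordinates (row 1 = northernmost)
  px <- raster$xll + (seq_len(ncp) - 0.5) * raster$cellsize
  py <- raster$yll + (nr - seq_len(nr) + 0.5) * raster$cellsize
  x <- rep(px, each = nr); y <- rep(py, times = ncp)
  v <- as.vector(raster$data)

  gx <- floor((x - grid$xll) / grid$cell_size)   # grid column, 0-based
  gy <- floor((y - grid$yll) / grid$cell_size)   # row from bottom
  inside <- gx >= 0 & gx < grid$cols & gy >= 0 & gy < grid$rows
  if (!any(inside))
    stop("no raster pixel centres fall inside the grid; frame mismatch?")
  grow <- grid$rows - 1 - gy                     # 0-based row from top
  id <- cell_id(grow, gx, grid$cols)
  ok <- inside & !is.na(v)
  sums <- rep(0, n_cells(grid)); cnts <- rep(0L, n_cells(grid))
  agg_s <- tapply(v[ok], id[ok], sum)
  agg_n <- tapply(v[ok], id[ok], length)
  idx <- as.integer(names(agg_s)) + 1L
  sums[idx] <- agg_s; cnts[idx] <- agg_n
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
  grid_layer(vals, grid, name, units)
}

#' Historical change layer: present minus past
#'
#' @param present,past [grid_layer()]s on the same grid and units.
#' @return A [grid_layer()] of `present - past`; masked wherever either
#'   input is masked.
#' @export
change_layer <- function(present, past) {
  stopifnot(inherits(present, "grid_layer"), inherits(past, "grid_layer"))
  if (!identical(unclass(present$grid), unclass(past$grid)))
    stop("layers are on different grids")
  if (!identical(present$units, past$units))
    stop("unit mismatch: ", present$units, " vs ", past$units)
  grid_layer(present$values - past$values, present$grid,
             paste0(present$name, "_change"), present$units)
}

#' Discard cells whose mean past elevation is negative
#'
#' Cells that were below sea level in the palaeo-reconstruction are removed
#' so that comparisons only span cells with land at both time points.
#'
#' @param past_elev Past-elevation [grid_layer()] in metres.
#' @param cells Candidate cell ids (default: all unmasked cells).
#' @param denominator `"candidates"` (default) or `"grid"`: base of the
#'   reported discarded fraction.
#' @return List with `retained` (cell ids), `discarded` (cell ids) and
#'   `fraction_discarded`.
#' @export
discard_submerged <- function(past_elev, cells = NULL,
                              denominator = c("candidates", "grid")) {
  stopifnot(inherits(past_elev, "grid_layer"))
  denominator <- match.arg(denominator)
  if (is.null(cells))
    cells <- which(!is.na(past_elev$values)) - 1L
  vals <- past_elev$values[cells + 1L]
  sub <- !is.na(vals) & vals < 0
  base <- if (denominator == "grid") n_cells(past_elev$grid) else length(cells)
  list(retained = cells[!sub], discarded = cells[sub],
       fraction_discarded = sum(sub) / base)
}

#' Classify cells as uplift or erosion from the elevation-change layer
#'
#' Positive change is uplift, negative is erosion; exact zeros belong to
#' neither class and are reported separately (with a message).
#'
#' @param elev_change Elevation-change [grid_layer()] (m).
#' @param cells Cell ids to classify (default: unmasked cells).
#' @return List with integer id vectors `uplift`, `erosion`, `excluded`.
#' @export
classify_cells <- function(elev_change, cells = NULL) {
  stopifnot(inherits(elev_change, "grid_layer"))
  if (is.null(cells))
    cells <- which(!is.na(elev_change$values)) - 1L
  d <- elev_change$values[cells + 1L]
  if (anyNA(d)) { cells <- cells[!is.na(d)]; d <- d[!is.na(d)] }
  zero <- d == 0
  if (any(zero))
    message(sum(zero), " cell(s) with exactly zero elevation change excluded",
            " from both classes")
  list(uplift = cells[d > 0], erosion = cells[d < 0], excluded = cells[zero])
}

#' Assemble the per-cell analysis table
#'
#' Joins assemblage rates and landscape layers into one row per retained
#' cell with the variables of the path model.
#'
#' @param cell_rates A `cell_rates` data frame.
#' @param elev_now,elev_change,t_now,t_change [grid_layer()]s.
#' @param cells Cell ids to keep (e.g. after submerged-cell discard and
#'   taxon filters); default: cells present in `cell_rates`.
#' @param rate_column Which assemblage mean becomes the response:
#'   `"weighted_geometric_mean_lambda"` (default; its log is the weighted
#'   mean log rate) or `"weighted_mean_lambda"`.
#' @return A `cell_table` data frame: `cell_id`, `elev_now`, `elev_change`,
#'   `t_now`, `t_change`, `lambda`, `log_lambda`, `class`.
#' @export
build_cell_table <- function(cell_rates, elev_now, elev_change, t_now,
                             t_change,
                             cells = cell_rates$cell_id,
                             rate_column = c("weighted_geometric_mean_lambda",
                                             "weighted_mean_lambda")) {
  rate_column <- match.arg(rate_column)
  keep <- intersect(cells, cell_rates$cell_id)
  d <- cell_rates[match(keep, cell_rates$cell_id), , drop = FALSE]
  out <- data.frame(
    cell_id = as.integer(keep),
    elev_now = elev_now$values[keep + 1L],
    elev_change = elev_change$values[keep + 1L],
    t_now = t_now$values[keep + 1L],
    t_change = t_change$values[keep + 1L],
    n_species = d$n_species,
    lambda = d[[rate_column]])
  ok <- complete.cases(out)
  if (!all(ok)) out <- out[ok, , drop = FALSE]
  out$log_lambda <- log(out$lambda)
  out$class <- ifelse(out$elev_change > 0, "uplift",
                      ifelse(out$elev_change < 0, "erosion", "none"))
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}
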