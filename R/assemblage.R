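#' Read a species range table
#'
#' Ranges are canonical as cell sets: a TSV with columns `species_id`,
#' `cell_id` (0-based row-major) and optionally `taxon_group`.
#'
#' @param path TSV path.
#' @param grid Optional [grid_spec()] used to bounds-check cell ids.
#' @return A data frame with columns `species_id`, `cell_id`, `taxon_group`.
#' @export
read_ranges <- function(path, grid = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "cell_id") %in% names(d)))
    stop("range table needs columns species_id and cell_id: ", path)
  if (is.null(d$taxon_group)) d$taxon_group <- "all"
  d$cell_id <- as.integer(d$cell_id)
  if (anyNA(d$cell_id)) stop("non-integer cell ids in ", path)
  if (!is.null(grid) && any(d$cell_id < 0 | d$cell_id >= n_cells(grid)))
    stop("cell ids outside grid bounds in ", path)
  d <- unique(d[, c("species_id", "cell_id", "taxon_group")])
  if (!nrow(d)) stop("empty range table: ", path)
  d
}

#' Range sizes (number of occupied grid cells per species)
#'
#' @param ranges Data frame with `species_id` and `cell_id`.
#' @return Named integer vector: cells occupied per species.
#' @export
range_sizes <- function(ranges) {
  stopifnot(all(c("species_id", "cell_id") %in% names(ranges)))
  tab <- table(unique(ranges[, c("species_id", "cell_id")])$species_id)
  setNames(as.integer(tab), names(tab))
}

#' Range-weighted assemblage speciation rates per grid cell
#'
#' For each occupied cell, computes the arithmetic and geometric mean of the
#' occupants' speciation rates, each species weighted by the inverse of its
#' range size so widespread species contribute less:
#' `w_i = 1/n_i`, arithmetic `sum(w*lambda)/sum(w)`, geometric
#' `exp(sum(w*log lambda)/sum(w))`.
#'
#' Species with a range but no rate are dropped with a warning (mirroring
#' taxonomic matching against the tree); species with a rate but no range
#' are silently unused.
#'
#' @param ranges Range table (`species_id`, `cell_id`, optional
#'   `taxon_group`).
#' @param rates A `tip_rates` table; all `lambda` must be > 0.
#' @return A `cell_rates` data frame: `cell_id`, `weighted_mean_lambda`,
#'   `weighted_geometric_mean_lambda`, `n_species`.
#' @examples
#' rng <- data.frame(species_id = c("a", "b"), cell_id = c(0L, 0L))
#' rts <- data.frame(species_id = c("a", "b"), lambda = c(0.2, 0.4))
#' weighted_cell_rates(rng, rts)
#' @export
weighted_cell_rates <- function(ranges, rates) {
  stopifnot(all(c("species_id", "lambda") %in% names(rates)))
  if (any(rates$lambda <= 0))
    stop("non-positive rate(s); geometric mean undefined for: ",
         paste(rates$species_id[rates$lambda <= 0], collapse = ", "))
  missing_rate <- setdiff(unique(ranges$species_id), rates$species_id)
  if (length(missing_rate)) {
    warning(length(missing_rate),
            " ranged species without a tip rate dropped: ",
            paste(head(missing_rate, 5), collapse = ", "),
            if (length(missing_rate) > 5) ", ...")
    ranges <- ranges[!ranges$species_id %in% missing_rate, , drop = FALSE]
  }
  if (!nrow(ranges)) stop("no ranged species with rates remain")

  nsz <- range_sizes(ranges)
  lam <- setNames(rates$lambda, rates$species_id)
  d <- unique(ranges[, c("species_id", "cell_id")])
  d$w <- 1 / nsz[d$species_id]
  d$lambda <- lam[d$species_id]

  sw <- tapply(d$w, d$cell_id, sum)
  swl <- tapply(d$w * d$lambda, d$cell_id, sum)
  swll <- tapply(d$w * log(d$lambda), d$cell_id, sum)
  nsp <- tapply(d$w, d$cell_id, length)
  out <- data.frame(
    cell_id = as.integer(names(sw)),
    weighted_mean_lambda = as.numeric(swl / sw),
    weighted_geometric_mean_lambda = as.numeric(exp(swll / sw)),
    n_species = as.integer(nsp))
  out <- out[order(out$cell_id), ]
  rownames(out) <- NULL
  class(out) <- c("cell_rates", "data.frame")
  out
}

#' Filter cells by taxon-group occupancy
#'
#' Retains exactly the cells occupied by at least one species of *every*
#' required taxon group (e.g. at least one mammal and one bird).
#'
#' @param ranges Range table with a `taxon_group` column.
#' @param required_groups Character vector of groups that must each be
#'   present in a retained cell.
#' @return Sorted integer vector of retained cell ids.
#' @export
filter_cells <- function(ranges, required_groups) {
  stopifnot(length(required_groups) >= 1,
            "taxon_group" %in% names(ranges))
  per_group <- lapply(required_groups, function(g)
    unique(ranges$cell_id[ranges$taxon_group == g]))
  sort(Reduce(intersect, per_group))
}

#' @rdname weighted_cell_rates
#' @param cell_rates A `cell_rates` data frame.
#' @param path Output TSV path.
#' @export
write_cell_rates <- function(cell_rates, path) {
  write.table(cell_rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
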