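#' Simulate contiguous species ranges and propagate tip rates
#'
#' Each tip of the phylogeny is assigned a spatially contiguous blob of grid
#' cells grown by seeded random accretion under rook adjacency, with size
#' drawn as `1 + Geometric` with mean `config$range_size_mean`.  The species'
#' tip rate is then `exp(mean latent log-speciation over its range +
#' Gaussian noise of sd config$tip_rate_noise_sd)`, linking the tip-rate
#' table to the landscape's latent field.  Cells occupied by no species are
#' reported in `empty_cells` and simply fall out of downstream assemblage
#' tables.
#'
#' @param config A [sim_config()].
#' @param phylogeny A `phylo` whose tips are the species (labels used as ids).
#' @param landscape Result of [simulate_landscape()] (supplies the grid and
#'   the latent field).
#' @param seed Optional integer overriding `config$seed + 1`.
#' @param taxon_group Group label attached to every species (single-group
#'   worlds by default; multi-group worlds are built by merging).
#' @return A list with `ranges` (data frame `species_id`, `cell_id`,
#'   `taxon_group`), `tip_rates` (a `tip_rates` data frame with statistic
#'   `"lambda_synthetic"`), and `empty_cells` (integer ids).
#' @export
simulate_ranges <- function(config, phylogeny, landscape, seed = NULL,
                            taxon_group = "all") {
  stopifnot(inherits(config, "sim_config"), inherits(phylogeny, "phylo"))
  grid <- landscape$grid
  latent <- landscape$truth$latent_log_lambda
  n <- n_cells(grid)
  species <- phylogeny$tip.label
  set.seed(seed %||% (config$seed + 1L))

  mean_extra <- config$range_size_mean - 1
  sizes <- if (mean_extra <= 0) rep(1L, length(species)) else
    1L + rgeom(length(species), prob = 1 / (1 + mean_extra))
  sizes <- pmin(sizes, n)
  if (sum(sizes) > 50L * n)
    stop("grid too small for requested total occupancy (",
         sum(sizes), " cell-occupancies on ", n, " cells)")

  occ <- vector("list", length(species))
  for (s in seq_along(species))
    occ[[s]] <- grow_blob(sizes[s], grid)
  ranges <- data.frame(
    species_id = rep(species, lengths(occ)),
    cell_id = unlist(occ),
    taxon_group = taxon_group, stringsAsFactors = FALSE)

  mean_latent <- vapply(occ, function(cells) mean(latent[cells + 1L]), 0)
  lam <- exp(mean_latent + rnorm(length(species), 0, config$tip_rate_noise_sd))
  rates <- data.frame(species_id = species, lambda = lam,
                      statistic = "lambda_synthetic", stringsAsFactors = FALSE)
  class(rates) <- c("tip_rates", "data.frame")

  empty <- setdiff(seq_len(n) - 1L, unique(ranges$cell_id))
  list(ranges = ranges, tip_rates = rates, empty_cells = empty)
}

## Random-walk accretion of a contiguous blob (rook adjacency), 0-based ids.
grow_blob <- function(size, grid) {
  start <- sample.int(n_cells(grid), 1L) - 1L
  if (size == 1L) return(start)
  blob <- integer(size); blob[1] <- start
  frontier <- rook_neighbours(start, grid)
  for (k in 2:size) {
    frontier <- setdiff(frontier, blob[seq_len(k - 1L)])
    if (!length(frontier)) { blob <- blob[seq_len(k - 1L)]; break }
    nxt <- frontier[sample.int(length(frontier), 1L)]
    blob[k] <- nxt
    frontier <- union(frontier, rook_neighbours(nxt, grid))
  }
  unique(blob)
}

rook_neighbours <- function(id, grid) {
  r <- cell_row(id, grid$cols); cc <- cell_col(id, grid$cols)
  nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
  ok <- nb[, 1] >= 0 & nb[, 1] < grid$rows & nb[, 2] >= 0 & nb[, 2] < grid$cols
  cell_id(nb[ok, 1], nb[ok, 2], grid$cols)
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper running [simulate_tree()], [simulate_landscape()] and
#' [simulate_ranges()] under one config and seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with `tree`, `layers`, `grid`, `truth`, `ranges`,
#'   `tip_rates`, `empty_cells`.
#' @export
simulate_world <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  tree <- simulate_tree(config, seed = seed)
  land <- simulate_landscape(config, seed = seed)
  rng <- simulate_ranges(config, tree, land, seed = seed + 1L)
  c(list(tree = tree), land, rng)
}

#' Write synthetic-world artifacts to disk
#'
#' Writes the tree (Newick), ranges (TSV), the four landscape layers (ESRI
#' ASCII grids), the tip-rate table (TSV) and the ground truth (JSON).
#'
#' @param world Result of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             ranges = file.path(dir, "ranges.tsv"),
             tip_rates = file.path(dir, "tip_rates.tsv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(world$tree, paths[["tree"]])
  write.table(world$ranges, paths[["ranges"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tip_rates(world$tip_rates, paths[["tip_rates"]])
  for (nm in names(world$layers)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(world$layers[[nm]], p)
    paths[[nm]] <- p
  }
  tr <- world$truth
  jsonlite::write_json(
    list(true_betas = as.list(tr$true_betas), sar_lambda = tr$sar_lambda,
         noise_sd = as.list(tr$noise_sd), affine = tr$affine,
         seed = tr$seed, latent_log_lambda = tr$latent_log_lambda),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
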