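# Shared fixtures and independent oracles.

# Brute-force equal-splits oracle: climb tip -> root accumulating
# l_j * 2^-(j-1).  Deliberately a different route from the package's
# top-down recursion.
oracle_es <- function(phy, tip) {
  ntip <- length(phy$tip.label)
  node <- match(tip, phy$tip.label)
  root <- ntip + 1L
  es <- 0; j <- 0L
  while (node != root) {
    k <- which(phy$edge[, 2] == node)
    es <- es + phy$edge.length[k] * 2^(-j)
    node <- phy$edge[k, 1]
    j <- j + 1L
  }
  es
}

random_bd_tree <- function(n, seed) {
  set.seed(seed)
  birth <- runif(1, 0.1, 0.5)
  death <- runif(1, 0, 0.8) * birth
  ape::rphylo(n, birth, death, fossils = FALSE)
}

# Inverse-range-weighted cell means recomputed from first principles.
oracle_cell_means <- function(ranges, rates) {
  lam <- setNames(rates$lambda, rates$species_id)
  d <- unique(ranges[, c("species_id", "cell_id")])
  sizes <- table(d$species_id)
  out <- lapply(split(d$species_id, d$cell_id), function(sp) {
    w <- 1 / as.numeric(sizes[sp])
    l <- lam[sp]
    c(am = sum(w * l) / sum(w), gm = exp(sum(w * log(l)) / sum(w)))
  })
  data.frame(cell_id = as.integer(names(out)),
             am = vapply(out, `[[`, 0, "am"),
             gm = vapply(out, `[[`, 0, "gm"), row.names = NULL)
}

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_tips = 150, grid_rows = 20, grid_cols = 20,
                        seed = 42L)
      cache <<- simulate_world(cfg)
    }
    cache
  }
})

landscape_frame <- function(seed, config = sim_config(seed = seed)) {
  land <- simulate_landscape(config, seed = seed)
  list(data = as.data.frame(land$truth$fields), land = land)
}
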