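test_that("range blobs are contiguous, in bounds, and deterministic", {
  cfg <- sim_config(n_tips = 80, grid_rows = 15, grid_cols = 15, seed = 2)
  tree <- simulate_tree(cfg)
  land <- simulate_landscape(cfg)
  a <- simulate_ranges(cfg, tree, land)
  b <- simulate_ranges(cfg, tree, land)
  expect_identical(a$ranges, b$ranges)
  expect_identical(a$tip_rates$lambda, b$tip_rates$lambda)
  expect_true(all(a$ranges$cell_id >= 0 & a$ranges$cell_id < 225))
  # rook contiguity of every range
  for (sp in sample(unique(a$ranges$species_id), 20)) {
    cells <- a$ranges$cell_id[a$ranges$species_id == sp]
    if (length(cells) == 1) next
    visited <- cells[1]
    frontier <- cells[1]
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, topospec:::rook_neighbours,
                                 grid = land$grid)))
      frontier <- setdiff(intersect(nb, cells), visited)
      visited <- union(visited, frontier)
    }
    expect_setequal(visited, cells)
  }
})

test_that("degenerate single-cell ranges propagate the latent field exactly", {
  cfg <- sim_config(n_tips = 120, grid_rows = 12, grid_cols = 12,
                    range_size_mean = 1, tip_rate_noise_sd = 0, seed = 4)
  tree <- simulate_tree(cfg)
  land <- simulate_landscape(cfg)
  rr <- simulate_ranges(cfg, tree, land)
  sizes <- range_sizes(rr$ranges)
  expect_true(all(sizes == 1L))
  cr <- weighted_cell_rates(rr$ranges, rr$tip_rates)
  latent <- land$truth$latent_log_lambda[cr$cell_id + 1L]
  expect_equal(log(cr$weighted_geometric_mean_lambda), latent,
               tolerance = 1e-9)
  expect_equal(log(cr$weighted_mean_lambda), latent, tolerance = 1e-9)
})

test_that("single-cell ranges with noise give exp(latent + noise) rates", {
  cfg <- sim_config(n_tips = 50, grid_rows = 10, grid_cols = 10,
                    range_size_mean = 1, tip_rate_noise_sd = 0.3, seed = 8)
  tree <- simulate_tree(cfg)
  land <- simulate_landscape(cfg)
  rr <- simulate_ranges(cfg, tree, land)
  latent_at <- land$truth$latent_log_lambda[rr$ranges$cell_id + 1L]
  noise <- log(rr$tip_rates$lambda[match(rr$ranges$species_id,
                                         rr$tip_rates$species_id)]) -
    latent_at
  expect_equal(sd(noise), 0.3, tolerance = 0.12)
})

test_that("cell-level log rates track the latent field across seeds", {
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 700 + s)
    world <- simulate_world(cfg)
    cr <- weighted_cell_rates(world$ranges, world$tip_rates)
    cor(log(cr$weighted_geometric_mean_lambda),
        world$truth$latent_log_lambda[cr$cell_id + 1L])
  }, 0)
  expect_true(all(rs > 0.5))
  expect_gt(mean(rs), 0.6)
})

test_that("impossible occupancy demands are refused", {
  cfg <- sim_config(n_tips = 500, grid_rows = 2, grid_cols = 2,
                    range_size_mean = 4, seed = 1)
  tree <- simulate_tree(cfg)
  land <- simulate_landscape(cfg)
  expect_error(simulate_ranges(cfg, tree, land), "too small")
})

test_that("world artifacts round-trip through plain-text formats", {
  w <- small_world()
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  tree <- read_newick(paths[["tree"]])
  expect_setequal(tree$tip.label, w$tree$tip.label)
  rng <- read_ranges(paths[["ranges"]], w$grid)
  expect_equal(nrow(rng), nrow(unique(w$ranges)))
  elev <- read_ascii_grid(paths[["elev_now"]])
  expect_equal(as.vector(t(elev$data)), w$layers$elev_now$values,
               tolerance = 1e-9)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$sar_lambda, w$truth$sar_lambda)
})
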