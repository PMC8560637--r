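test_that("range sizes are set cardinalities", {
  rng <- data.frame(species_id = c("a", "b", "b", "b", "b", "b"),
                    cell_id = c(3L, 0L, 1L, 2L, 7L, 7L))
  sz <- range_sizes(rng)
  expect_equal(sz[["a"]], 1L)
  expect_equal(sz[["b"]], 4L)  # duplicate occupancy records collapse
  w <- small_world()
  sz2 <- range_sizes(w$ranges)
  brute <- vapply(split(w$ranges$cell_id, w$ranges$species_id),
                  function(x) length(unique(x)), 0L)
  expect_equal(sz2[names(brute)], brute)
})

test_that("weighted cell means match hand computation", {
  rng <- data.frame(species_id = c("a", "b", "b", "b", "b"),
                    cell_id = c(0L, 0L, 1L, 2L, 3L))
  rts <- data.frame(species_id = c("a", "b"), lambda = c(0.2, 0.4))
  cr <- weighted_cell_rates(rng, rts)
  c0 <- cr[cr$cell_id == 0, ]
  expect_equal(c0$weighted_mean_lambda, (0.2 * 1 + 0.4 * 0.25) / 1.25)
  expect_equal(c0$weighted_geometric_mean_lambda,
               exp((log(0.2) + 0.25 * log(0.4)) / 1.25), tolerance = 1e-12)
  expect_equal(c0$n_species, 2L)
  # single-occupant cells: both means equal the occupant's rate
  expect_equal(cr$weighted_mean_lambda[cr$cell_id == 1], 0.4)
  expect_equal(cr$weighted_geometric_mean_lambda[cr$cell_id == 1], 0.4)
})

test_that("equal range sizes reduce the weighted mean to the plain mean", {
  rng <- data.frame(species_id = rep(c("a", "b", "c"), each = 2),
                    cell_id = c(0L, 1L, 0L, 2L, 0L, 3L))
  rts <- data.frame(species_id = c("a", "b", "c"),
                    lambda = c(0.1, 0.2, 0.6))
  cr <- weighted_cell_rates(rng, rts)
  expect_equal(cr$weighted_mean_lambda[cr$cell_id == 0], mean(rts$lambda))
})

test_that("weighted means agree with a brute-force oracle and obey AM-GM", {
  for (s in 1:50) {
    set.seed(s)
    nsp <- sample(5:25, 1)
    rng <- data.frame(
      species_id = rep(paste0("sp", seq_len(nsp)),
                       times = sample(1:6, nsp, replace = TRUE)))
    rng$cell_id <- sample(0:15, nrow(rng), replace = TRUE)
    rng <- unique(rng)
    rts <- data.frame(species_id = paste0("sp", seq_len(nsp)),
                      lambda = exp(rnorm(nsp, -1, 0.7)))
    cr <- weighted_cell_rates(rng, rts)
    orc <- oracle_cell_means(rng, rts)
    expect_equal(cr$weighted_mean_lambda, orc$am, tolerance = 1e-12)
    expect_equal(cr$weighted_geometric_mean_lambda, orc$gm,
                 tolerance = 1e-12)
    expect_true(all(cr$weighted_geometric_mean_lambda <=
                      cr$weighted_mean_lambda + 1e-12))
    # both means bounded by member rates
    lam <- setNames(rts$lambda, rts$species_id)
    for (cid in cr$cell_id) {
      members <- lam[rng$species_id[rng$cell_id == cid]]
      expect_gte(cr$weighted_mean_lambda[cr$cell_id == cid] + 1e-12,
                 min(members))
      expect_lte(cr$weighted_geometric_mean_lambda[cr$cell_id == cid] - 1e-12,
                 max(members))
    }
  }
})

test_that("widening a species' range damps its influence on a cell", {
  rts <- data.frame(species_id = c("rare", "wide"), lambda = c(0.1, 0.8))
  base <- data.frame(species_id = c("rare", "wide"), cell_id = c(0L, 0L))
  m_prev <- weighted_cell_rates(base, rts)$weighted_mean_lambda[1]
  for (extra in 1:4) {
    rng <- rbind(base, data.frame(species_id = "wide",
                                  cell_id = seq_len(extra)))
    m <- weighted_cell_rates(rng, rts)
    m0 <- m$weighted_mean_lambda[m$cell_id == 0]
    expect_lt(m0, m_prev)      # moves toward the rare species' 0.1
    expect_gt(m0, 0.1)
    m_prev <- m0
  }
})

test_that("taxon-group filter retains exactly jointly occupied cells", {
  rng <- data.frame(
    species_id = c("m1", "m2", "b1", "b2"),
    cell_id = c(0L, 1L, 1L, 2L),
    taxon_group = c("mammal", "mammal", "bird", "bird"))
  expect_equal(filter_cells(rng, c("mammal", "bird")), 1L)
  expect_equal(filter_cells(rng, "mammal"), c(0L, 1L))
  for (s in 1:10) {
    set.seed(100 + s)
    rng2 <- data.frame(
      species_id = paste0("sp", 1:30),
      cell_id = sample(0:20, 30, replace = TRUE),
      taxon_group = sample(c("mammal", "bird"), 30, replace = TRUE))
    got <- filter_cells(rng2, c("mammal", "bird"))
    brute <- intersect(rng2$cell_id[rng2$taxon_group == "mammal"],
                       rng2$cell_id[rng2$taxon_group == "bird"])
    expect_equal(got, sort(brute))
  }
})

test_that("rate/range mismatches follow the drop rules", {
  rng <- data.frame(species_id = c("a", "ghost"), cell_id = c(0L, 1L))
  rts <- data.frame(species_id = c("a", "unranged"), lambda = c(0.2, 0.3))
  expect_warning(cr <- weighted_cell_rates(rng, rts), "ghost")
  expect_equal(cr$cell_id, 0L)
  expect_error(
    weighted_cell_rates(rng,
                        data.frame(species_id = c("a", "ghost"),
                                   lambda = c(0.2, -1))),
    "ghost")
})

test_that("recomputation is bit-identical", {
  w <- small_world()
  a <- weighted_cell_rates(w$ranges, w$tip_rates)
  b <- weighted_cell_rates(w$ranges, w$tip_rates)
  expect_identical(a, b)
})
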