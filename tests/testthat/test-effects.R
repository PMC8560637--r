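chain_B <- function(a = 0.5, b = 0.4, c = 0.2) {
  B <- matrix(0, 3, 3, dimnames = list(c("x", "m", "y"), c("x", "m", "y")))
  B["m", "x"] <- a; B["y", "m"] <- b; B["y", "x"] <- c
  B
}

# Independent oracle: enumerate all simple directed paths recursively,
# written without reference to the package's internals.
oracle_total <- function(B, from, to) {
  if (from == to) return(1)
  kids <- rownames(B)[B[, from] != 0]
  if (!length(kids)) return(0)
  sum(vapply(kids, function(k) B[k, from] * oracle_total(B, k, to), 0))
}

test_that("the mediation chain decomposes exactly", {
  eff <- decompose_effects(chain_B(), "y")
  x <- eff[eff$source == "x", ]
  expect_identical(x$direct, 0.2)
  expect_identical(x$indirect, 0.5 * 0.4)
  expect_equal(x$total, 0.4, tolerance = 1e-15)
  m <- eff[eff$source == "m", ]
  expect_equal(m$total, m$direct)  # no mediators below m
})

test_that("path enumeration equals the matrix inverse on random DAGs", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:8, 1)
    nodes <- paste0("v", seq_len(n))
    B <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (i in 2:n) for (j in 1:(i - 1))
      if (runif(1) < 0.5) B[i, j] <- runif(1, -0.8, 0.8)
    eff <- decompose_effects(B, nodes[n])
    for (k in seq_len(n - 1)) {
      expect_equal(eff$total[k], oracle_total(B, nodes[k], nodes[n]),
                   tolerance = 1e-12)
      expect_identical(eff$total[k], eff$direct[k] + eff$indirect[k])
    }
  }
  Bcyc <- chain_B(); Bcyc["x", "y"] <- 0.3
  expect_error(decompose_effects(Bcyc, "y"), "cyclic")
})

test_that("group effects sum their members", {
  lf <- landscape_frame(53)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  pf <- fit_path_model(default_path_spec(), list(data = lf$data), w)
  eff <- total_effects(pf)
  pick <- function(t) eff$total[eff$term == t]
  expect_equal(pick("elevation"), pick("elev_change") + pick("elev_now"),
               tolerance = 1e-12)
  expect_equal(pick("temperature"), pick("t_change") + pick("t_now"),
               tolerance = 1e-12)
  expect_equal(pick("historical"), pick("elev_change") + pick("t_change"),
               tolerance = 1e-12)
  expect_equal(pick("present"), pick("elev_now") + pick("t_now"),
               tolerance = 1e-12)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-15)
})

test_that("Monte-Carlo intervals degenerate without coefficient noise", {
  lf <- landscape_frame(59)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  pf <- fit_path_model(default_path_spec(), list(data = lf$data), w)
  for (r in names(pf$fits)) pf$fits[[r]]$vcov_beta[] <- 0
  eff <- suppressWarnings(effect_uncertainty(pf, n_draws = 120, seed = 1))
  expect_equal(eff$total_lo, eff$total, tolerance = 1e-12)
  expect_equal(eff$total_hi, eff$total, tolerance = 1e-12)
})

test_that("interval width grows with either coefficient's uncertainty", {
  lf <- landscape_frame(61)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  spec <- path_model_spec(c("elev_now ~ elev_change",
                            "log_lambda ~ elev_now"))
  pf <- fit_path_model(spec, list(data = lf$data), w)
  width <- function(fit) {
    e <- effect_uncertainty(fit, n_draws = 400, seed = 7)
    row <- e[e$term == "elev_change", ]
    row$total_hi - row$total_lo
  }
  w0 <- width(pf)
  for (eq in c("elev_now", "log_lambda")) {
    pf2 <- pf
    pf2$fits[[eq]]$vcov_beta <- pf$fits[[eq]]$vcov_beta * 9
    expect_gt(width(pf2), w0)
  }
})

test_that("percent change per s.d. follows the closed form", {
  expect_identical(percent_change_per_sd(0, 1.3), 0)
  expect_equal(percent_change_per_sd(0.1, 1), 100 * (exp(0.1) - 1),
               tolerance = 1e-12)  # 10.517%
  expect_equal(percent_change_per_sd(-0.1, 1), 100 * (exp(-0.1) - 1),
               tolerance = 1e-12)  # -9.516%
})

test_that("the display filter suppresses but never deletes", {
  eff <- data.frame(term = c("big", "small", "zero"), kind = "predictor",
                    direct = 0, indirect = 0,
                    total = c(log(1.11), log(1.02), 0))
  out <- display_filter(eff, sd_log_lambda = 1, threshold_pct = 5)
  expect_equal(nrow(out), 3)
  expect_equal(out$suppressed, c(FALSE, TRUE, TRUE))
  expect_equal(out$percent_per_sd[1], 11, tolerance = 1e-9)
  all_kept <- display_filter(eff, 1, threshold_pct = 0)
  expect_false(any(all_kept$suppressed))
})
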