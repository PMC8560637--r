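test_that("path specifications are parsed and validated", {
  spec <- path_model_spec(c("m ~ x", "y ~ x + m"))
  expect_equal(spec$equations$y, c("x", "m"))
  expect_equal(spec$nodes, c("x", "m", "y"))
  expect_error(path_model_spec(c("y ~ x", "x ~ y")), "bidirectional")
  expect_error(path_model_spec("y ~ y"), "self-loop")
  expect_error(path_model_spec(c("y ~ x", "y ~ m")), "duplicate response")
  expect_error(path_model_spec("y x"), "malformed")
})

test_that("the default model has the added elevation-to-temperature link", {
  spec <- default_path_spec()
  expect_true("elev_change" %in% spec$equations$t_now)
  expect_false("elev_change" %in%
                 default_path_spec(FALSE)$equations$t_now)
  # exactly one non-adjacent pair remains: (elev_now, t_change)
  claims <- topospec:::basis_set(spec)
  expect_length(claims, 1)
  expect_setequal(c(claims[[1]]$u, claims[[1]]$v),
                  c("elev_now", "t_change"))
  expect_equal(claims[[1]]$conditioning, "elev_change")
})

test_that("single-equation model reduces to a direct SAR fit", {
  lf <- landscape_frame(17)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  spec <- path_model_spec("log_lambda ~ elev_change")
  pf <- fit_path_model(spec, list(data = lf$data), w)
  direct <- fit_sar_error(lf$data$log_lambda,
                          as.matrix(lf$data["elev_change"]), w)
  expect_equal(pf$fits$log_lambda$beta, direct$beta)
  expect_equal(pf$fits$log_lambda$lambda_sar, direct$lambda_sar)
})

test_that("equation order does not change the fits", {
  lf <- landscape_frame(23)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  s1 <- path_model_spec(c("elev_now ~ elev_change",
                          "t_change ~ elev_change",
                          "t_now ~ elev_now + t_change + elev_change",
                          "log_lambda ~ elev_change + t_change + elev_now + t_now"))
  s2 <- path_model_spec(rev(c("elev_now ~ elev_change",
                              "t_change ~ elev_change",
                              "t_now ~ elev_now + t_change + elev_change",
                              "log_lambda ~ elev_change + t_change + elev_now + t_now")))
  f1 <- fit_path_model(s1, list(data = lf$data), w)
  f2 <- fit_path_model(s2, list(data = lf$data), w)
  for (r in names(f1$fits))
    expect_equal(f1$fits[[r]]$beta, f2$fits[[r]]$beta)
  e1 <- total_effects(f1); e2 <- total_effects(f2)
  expect_equal(e1[order(e1$term), ], e2[order(e2$term), ],
               ignore_attr = TRUE)
})

test_that("saturated models make the d-separation test vacuous", {
  lf <- landscape_frame(31)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  sat <- path_model_spec(c("b ~ a", "c ~ a + b"))
  d2 <- lf$data[, 1:3]
  names(d2) <- c("a", "b", "c")
  ds <- dsep_test(sat, list(data = d2), w)
  expect_equal(ds$fishers_C, 0)
  expect_equal(ds$df, 0L)
})

test_that("Fisher's C combines the claim p-values it reports", {
  lf <- landscape_frame(37)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  # a DAG with two missing edges gives two claims and df = 4
  spec <- path_model_spec(c("elev_now ~ elev_change",
                            "t_change ~ elev_change",
                            "t_now ~ elev_now + t_change",
                            "log_lambda ~ elev_change + t_change + elev_now + t_now"))
  ds <- dsep_test(spec, list(data = lf$data), w)
  expect_equal(nrow(ds$claims), 2)
  expect_equal(ds$df, 4L)
  expect_equal(ds$fishers_C, -2 * sum(log(ds$claims$p_value)),
               tolerance = 1e-12)
  expect_equal(ds$p_C, pchisq(ds$fishers_C, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("omitting a real link is detected as a missing path", {
  # generator includes elev_change -> t_now; the tested DAG omits it
  lf <- landscape_frame(41)
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  ds <- dsep_test(default_path_spec(FALSE), list(data = lf$data), w)
  expect_lt(ds$p_C, 0.01)
})

test_that("edge coefficients are recovered on latent-field data", {
  w <- build_weights(0:899, grid_spec(30, 30), "queen")
  spec <- default_path_spec()
  cfg <- sim_config(seed = 1)
  covered <- matrix(NA, 40, 4,
                    dimnames = list(NULL, spec$equations$log_lambda))
  for (s in seq_len(40)) {
    lf <- landscape_frame(500 + s)
    d <- lf$data
    d$log_lambda <- d$log_lambda / sd(d$log_lambda)  # standardized response
    for (v in names(d)) d[[v]] <- (d[[v]] - mean(d[[v]])) / sd(d[[v]])
    f <- fit_sar_error(d$log_lambda,
                       as.matrix(d[spec$equations$log_lambda]), w)
    for (p in spec$equations$log_lambda) {
      truth <- cfg$true_betas[[paste0(p, "->log_lambda")]] *
        sd(lf$data[[p]]) / sd(lf$data$log_lambda)
      covered[s, p] <- abs(f$beta[[p]] - truth) <= 1.96 * f$se_beta[[p]]
    }
  }
  expect_true(all(colMeans(covered) >= 0.85))
})
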