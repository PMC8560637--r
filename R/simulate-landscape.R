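#' Simulate landscape layers with a known causal structure
#'
#' Generates per-cell elevation and temperature layers (present and past)
#' whose standardized-scale relationships follow the package's hypothesised
#' causal DAG with the coefficients in `config$true_betas`:
#'
#' * `elev_change` — exogenous; white noise convolved with a Gaussian kernel
#'   of scale `config$smooth_sigma` cells (so uplift/erosion provinces are
#'   spatially coherent, as real topographic-change fields are), rescaled to
#'   sd 1 and mean `delta_mean`;
#' * `elev_now   <- elev_change`;
#' * `t_change   <- elev_change`;
#' * `t_now      <- elev_now + t_change + elev_change`;
#' * `log_lambda <- elev_change + t_change + elev_now + t_now`,
#'
#' each with independent Gaussian innovations except the `log_lambda`
#' equation, whose error follows a simultaneous autoregressive process
#' `u = sar_lambda * W u + eps` over queen-contiguity weights on the full
#' grid.  Layers are returned on physical scales (m, degrees C) via affine
#' maps recorded in the returned truth; past layers are defined as present
#' minus change so that downstream differencing recovers the change fields
#' exactly.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with `layers` (named list of [grid_layer()]s: `elev_now`,
#'   `elev_past`, `t_now`, `t_past`), `grid`, and `truth` (class
#'   `synthetic_truth`): standardized node fields, the latent log-speciation
#'   field, realized coefficients, `sar_lambda`, affine maps, seed.
#' @export
simulate_landscape <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  set.seed(seed)
  grid <- grid_spec(config$grid_rows, config$grid_cols, config$cell_size)
  n <- n_cells(grid)
  b <- config$true_betas
  ns <- config$noise_sd

  ## exogenous elevation-change field: smoothed white noise, sd 1
  raw <- matrix(rnorm(n), grid$rows, grid$cols)
  sm <- if (config$smooth_sigma > 0)
    gaussian_smooth(raw, sigma = config$smooth_sigma) else raw
  ec <- as.vector(t(sm))                      # row-major cell order
  ec <- (ec - mean(ec)) / sd(ec) + config$delta_mean

  en <- b[["elev_change->elev_now"]] * ec + rnorm(n, 0, ns[["elev_now"]])
  tc <- b[["elev_change->t_change"]] * ec + rnorm(n, 0, ns[["t_change"]])
  tn <- b[["elev_now->t_now"]] * en + b[["t_change->t_now"]] * tc +
    b[["elev_change->t_now"]] * ec + rnorm(n, 0, ns[["t_now"]])

  w <- build_weights(seq_len(n) - 1L, grid, "queen")
  eps <- rnorm(n, 0, ns[["log_lambda"]])
  u <- sar_error_draw(w, config$sar_lambda, eps)
  lz <- b[["elev_change->log_lambda"]] * ec + b[["t_change->log_lambda"]] * tc +
    b[["elev_now->log_lambda"]] * en + b[["t_now->log_lambda"]] * tn + u
  latent <- config$log_lambda_mean + config$log_lambda_scale * lz

  elev_now <- config$elev_mean + config$elev_sd * en
  elev_past <- elev_now - config$elev_sd * ec
  t_now <- config$temp_mean + config$temp_sd * tn
  t_past <- t_now - config$temp_sd * tc

  truth <- structure(list(
    fields = list(elev_change = ec, t_change = tc, elev_now = en,
                  t_now = tn, log_lambda = lz),
    latent_log_lambda = latent, sar_error = u,
    true_betas = b, sar_lambda = config$sar_lambda, noise_sd = ns,
    affine = list(elev = c(mean = config$elev_mean, sd = config$elev_sd),
                  temp = c(mean = config$temp_mean, sd = config$temp_sd),
                  log_lambda = c(mean = config$log_lambda_mean,
                                 sd = config$log_lambda_scale)),
    seed = seed), class = "synthetic_truth")

  list(layers = list(
         elev_now = grid_layer(elev_now, grid, "elev_now", "m"),
         elev_past = grid_layer(elev_past, grid, "elev_past", "m"),
         t_now = grid_layer(t_now, grid, "t_now", "degC"),
         t_past = grid_layer(t_past, grid, "t_past", "degC")),
       grid = grid, truth = truth)
}

## Separable Gaussian smoothing with edge renormalisation (kernel truncated
## at 3 sigma; convolving a ones-matrix supplies the per-cell normaliser).
gaussian_smooth <- function(m, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  conv1 <- function(mat, along_rows) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (o in -hw:hw) {
      wgt <- k[o + hw + 1]
      if (along_rows) {
        src <- seq_len(nrow(mat)) + o
        ok <- src >= 1 & src <= nrow(mat)
        out[ok, ] <- out[ok, ] + wgt * mat[src[ok], , drop = FALSE]
      } else {
        src <- seq_len(ncol(mat)) + o
        ok <- src >= 1 & src <= ncol(mat)
        out[, ok] <- out[, ok] + wgt * mat[, src[ok], drop = FALSE]
      }
    }
    out
  }
  num <- conv1(conv1(m, TRUE), FALSE)
  den <- conv1(conv1(matrix(1, nrow(m), ncol(m)), TRUE), FALSE)
  num / den
}

## Draw a SAR-correlated error: u = (I - lambda W)^{-1} eps.
sar_error_draw <- function(w, lambda, eps) {
  n <- length(eps)
  if (abs(lambda) >= 1)
    stop("(I - lambda W) is singular or non-stationary; sar_lambda = ",
         lambda)
  B <- Diagonal(n) - lambda * w$W
  u <- try(solve(B, eps), silent = TRUE)
  if (inherits(u, "try-error"))
    stop("(I - lambda W) is singular; sar_lambda = ", lambda)
  as.numeric(u)
}

#' True standardized total effect within a cell subset
#'
#' The synthetic world's structural coefficients are invariant under
#' selection on the exogenous elevation-change field, but *standardized*
#' effects are subset-relative.  This helper converts the known raw total
#' effect of a source node on the latent log speciation rate into the
#' standardized scale of a given subset: raw total effect on the structural
#' scale, times `log_lambda_scale`, times `sd(source)/sd(response)` computed
#' on the supplied per-cell data.
#'
#' @param truth A `synthetic_truth`.
#' @param source Source node name (e.g. `"elev_change"`).
#' @param subset_idx 1-based indices (into the full cell vector) of the
#'   analysed subset; the source sd is taken from the structural-scale field
#'   over these cells.
#' @param response_values Observed response (log rate) values in the subset,
#'   in the same cell order.
#' @param ranges Optional range table.  When the analysed response is an
#'   assemblage mean (species averaging the latent field over their ranges),
#'   the true marginal effect of a cell's own predictor value on its
#'   assemblage rate carries the known range-aggregation factor
#'   `kappa = cov(S f, f)/var(f)` within the subset, where `S` is the
#'   inverse-range-weighted aggregation operator implied by the ranges and
#'   `f` the source field; supplying `ranges` includes it.  Omit `ranges`
#'   when the response is the latent field itself.
#' @return The true standardized total effect (scalar).
#' @export
true_total_effect <- function(truth, source, subset_idx, response_values,
                              ranges = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  B <- betas_to_matrix(truth$true_betas)
  Tot <- solve(diag(nrow(B)) - B) - diag(nrow(B))
  raw <- Tot["log_lambda", source]
  f <- truth$fields[[source]]
  kappa <- if (is.null(ranges)) 1 else
    range_smoothing_factor(ranges, f, subset_idx)
  raw * kappa * truth$affine$log_lambda[["sd"]] *
    sd(f[subset_idx]) / sd(response_values)
}

#' Attenuation factor of the range-aggregation operator
#'
#' Assemblage rates average the latent field over occupants' ranges, so the
#' marginal dependence of a cell's assemblage log rate on its own value of a
#' spatial field is shrunk by `kappa = cov(S f, f) / var(f)` over the
#' analysed cells, where `S` is the row-stochastic aggregation operator
#' (species weighted by inverse range size, each species contributing its
#' range mean).
#'
#' @param ranges Range table (`species_id`, `cell_id`).
#' @param field Numeric field over all grid cells (full-length vector).
#' @param subset_idx 1-based cell indices of the analysed subset.
#' @return The scalar attenuation factor.
#' @export
range_smoothing_factor <- function(ranges, field, subset_idx) {
  d <- unique(ranges[, c("species_id", "cell_id")])
  nsz <- range_sizes(d)
  w <- 1 / nsz[d$species_id]                 # species weight in a cell
  rmean <- tapply(field[d$cell_id + 1L], d$species_id, mean)[d$species_id]
  num <- tapply(w * rmean, d$cell_id, sum)
  den <- tapply(w, d$cell_id, sum)
  sf <- setNames(as.numeric(num / den), names(num))  # (S f) per occupied cell
  idx0 <- as.character(subset_idx - 1L)
  ok <- idx0 %in% names(sf)
  if (!all(ok)) stop("subset contains unoccupied cell(s)")
  f_sub <- field[subset_idx]
  stats::cov(sf[idx0], f_sub) / var(f_sub)
}

## Structural coefficient matrix B[response, source] from a named beta vector.
betas_to_matrix <- function(betas) {
  nodes <- names(structural_parents())
  B <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (lbl in names(betas)) {
    p <- strsplit(lbl, "->", fixed = TRUE)[[1]]
    B[p[2], p[1]] <- betas[[lbl]]
  }
  B
}
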