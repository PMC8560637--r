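#' Configuration for the synthetic-world generator
#'
#' Bundles every parameter of the synthetic study system: a birth-death
#' phylogeny, a rectangular equal-area grid of cells, landscape layers
#' generated from a recursive structural model on standardized scales, and
#' species ranges that propagate a latent cell-level log-speciation field to
#' tip rates.
#'
#' The structural model has five nodes: elevation change (`elev_change`,
#' exogenous), temperature change (`t_change`), present elevation
#' (`elev_now`), present temperature (`t_now`) and the latent log speciation
#' rate (`log_lambda`).  `true_betas` holds the standardized-scale path
#' coefficients, named `"<source>-><response>"`.  Innovation standard
#' deviations for the three mediator equations default to values that give
#' each mediator unit marginal variance (so `true_betas` are population
#' standardized coefficients); the `log_lambda` equation's innovation sd is a
#' free parameter because its error is additionally SAR-correlated.
#'
#' @param n_tips Number of extant tips in the simulated phylogeny (>= 2).
#' @param birth_rate,death_rate Birth-death rates (events/lineage/Myr);
#'   `death_rate` must be strictly below `birth_rate`.
#' @param grid_rows,grid_cols Grid dimensions.
#' @param cell_size Nominal cell edge length in km (metadata only; the
#'   analysis is resolution-free).
#' @param true_betas Named numeric vector of structural path coefficients on
#'   standardized scales; see Details for the default DAG.
#' @param sar_lambda Spatial autocorrelation of the `log_lambda` equation's
#'   error, `abs(sar_lambda) < 1`.
#' @param noise_sd Named numeric vector of innovation sds per endogenous
#'   equation (`t_change`, `elev_now`, `t_now`, `log_lambda`).  `NA` entries
#'   for the mediators are replaced by the unit-variance defaults.
#' @param delta_mean Mean of the standardized elevation-change field; 0 gives
#'   roughly balanced uplift and erosion cell counts.
#' @param smooth_sigma Gaussian correlation scale (in cells) of the
#'   exogenous elevation-change field; the default of 4 cells (~400 km at
#'   the nominal resolution) emulates the continental-scale coherence of
#'   real uplift and erosion provinces.  0 gives a white-noise field.
#' @param range_size_mean Mean range size in cells; sizes are
#'   `1 + Geometric`, so `range_size_mean = 1` gives single-cell ranges.
#' @param tip_rate_noise_sd Sd of the lognormal noise on tip rates
#'   (dimensionless, on the log scale).
#' @param log_lambda_mean,log_lambda_scale Affine map from the standardized
#'   structural field to the latent log speciation rate:
#'   `latent = log_lambda_mean + log_lambda_scale * L_z`.
#' @param elev_mean,elev_sd,temp_mean,temp_sd Affine maps from standardized
#'   layers to physical scales (m, degrees C).  `elev_sd` defaults to 195 m,
#'   `temp_sd` to 5 degrees C.
#' @param seed Integer seed; identical configs reproduce identical worlds.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_tips = 50, grid_rows = 10, grid_cols = 10, seed = 1)
#' cfg$true_betas[["elev_change->log_lambda"]]
#' @export
sim_config <- function(n_tips = 300,
                       birth_rate = 0.2,
                       death_rate = 0,
                       grid_rows = 30,
                       grid_cols = 30,
                       cell_size = 100,
                       true_betas = default_true_betas(),
                       sar_lambda = 0.5,
                       noise_sd = c(t_change = NA, elev_now = NA,
                                    t_now = NA, log_lambda = 0.6),
                       delta_mean = 0,
                       smooth_sigma = 4,
                       range_size_mean = 4,
                       tip_rate_noise_sd = 0.2,
                       log_lambda_mean = log(0.2),
                       log_lambda_scale = 0.5,
                       elev_mean = 1000, elev_sd = 195,
                       temp_mean = 10, temp_sd = 5,
                       seed = 1L) {
  stopifnot(is.numeric(n_tips), length(n_tips) == 1, n_tips >= 2)
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be positive")
  if (!is.numeric(death_rate) || death_rate < 0)
    stop("death_rate must be non-negative")
  if (death_rate >= birth_rate)
    stop("death_rate must be strictly less than birth_rate")
  stopifnot(grid_rows >= 2, grid_cols >= 2, cell_size > 0)
  if (abs(sar_lambda) >= 1) stop("sar_lambda must lie in (-1, 1)")
  if (tip_rate_noise_sd < 0) stop("tip_rate_noise_sd must be >= 0")
  if (range_size_mean < 1) stop("range_size_mean must be >= 1")

  betas <- default_true_betas()
  if (!is.null(true_betas)) {
    unknown <- setdiff(names(true_betas), names(betas))
    if (length(unknown))
      stop("unknown path label(s): ", paste(unknown, collapse = ", "))
    betas[names(true_betas)] <- true_betas
  }

  ns <- c(t_change = NA_real_, elev_now = NA_real_, t_now = NA_real_,
          log_lambda = 0.6)
  if (!is.null(noise_sd)) {
    unknown <- setdiff(names(noise_sd), names(ns))
    if (length(unknown))
      stop("unknown noise_sd equation(s): ", paste(unknown, collapse = ", "))
    ns[names(noise_sd)] <- noise_sd
  }
  ns <- fill_unit_variance_noise(betas, ns)
  if (any(ns <= 0)) stop("all noise sds must be > 0")

  structure(list(
    n_tips = as.integer(n_tips), birth_rate = birth_rate,
    death_rate = death_rate, grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols), cell_size = cell_size,
    true_betas = betas, sar_lambda = sar_lambda, noise_sd = ns,
    delta_mean = delta_mean, smooth_sigma = smooth_sigma,
    range_size_mean = range_size_mean,
    tip_rate_noise_sd = tip_rate_noise_sd,
    log_lambda_mean = log_lambda_mean, log_lambda_scale = log_lambda_scale,
    elev_mean = elev_mean, elev_sd = elev_sd,
    temp_mean = temp_mean, temp_sd = temp_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default structural path coefficients of the synthetic world
#'
#' Standardized-scale coefficients for the hypothesised causal structure:
#' elevation change drives temperature change, present elevation and (via the
#' added link) present temperature; present elevation and temperature change
#' drive present temperature; and all four abiotic variables drive the latent
#' log speciation rate.
#'
#' @return Named numeric vector of path coefficients.
#' @export
default_true_betas <- function() {
  c("elev_change->elev_now"   =  0.5,
    "elev_change->t_change"   =  0.4,
    "elev_now->t_now"         = -0.5,
    "t_change->t_now"         =  0.3,
    "elev_change->t_now"      = -0.3,
    "elev_change->log_lambda" =  0.3,
    "t_change->log_lambda"    =  0.2,
    "elev_now->log_lambda"    =  0.15,
    "t_now->log_lambda"       =  0.2)
}

## Population covariance of the standardized node system, used to derive
## innovation sds that give mediators unit marginal variance.
structural_parents <- function() {
  list(elev_change = character(0),
       elev_now = "elev_change",
       t_change = "elev_change",
       t_now = c("elev_now", "t_change", "elev_change"),
       log_lambda = c("elev_change", "t_change", "elev_now", "t_now"))
}

fill_unit_variance_noise <- function(betas, ns) {
  pars <- structural_parents()
  nodes <- names(pars)
  Sigma <- diag(0, length(nodes))
  dimnames(Sigma) <- list(nodes, nodes)
  Sigma["elev_change", "elev_change"] <- 1
  for (nd in c("elev_now", "t_change", "t_now")) {
    pa <- pars[[nd]]
    b <- betas[paste0(pa, "->", nd)]
    expl <- drop(b %*% Sigma[pa, pa, drop = FALSE] %*% b)
    if (is.na(ns[[nd]])) {
      if (expl >= 1)
        stop("betas for ", nd, " explain variance >= 1; supply noise_sd")
      ns[[nd]] <- sqrt(1 - expl)
    }
    v <- expl + ns[[nd]]^2
    for (other in nodes) {
      Sigma[nd, other] <- Sigma[other, nd] <-
        if (other == nd) v else drop(b %*% Sigma[pa, other])
    }
  }
  ns
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-world configuration\n")
  cat(sprintf("  phylogeny: %d tips, birth %.3g, death %.3g /lineage/Myr\n",
              x$n_tips, x$birth_rate, x$death_rate))
  cat(sprintf("  grid: %d x %d cells of %g km; sar_lambda = %.2f\n",
              x$grid_rows, x$grid_cols, x$cell_size, x$sar_lambda))
  cat(sprintf("  ranges: mean %g cells; tip-rate noise sd %.2f; seed %d\n",
              x$range_size_mean, x$tip_rate_noise_sd, x$seed))
  invisible(x)
}
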