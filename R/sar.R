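#' Maximum-likelihood spatial simultaneous autoregressive (SAR) error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma2 I)` by
#' maximum likelihood.  The likelihood is concentrated over `lambda`: for
#' each candidate, `beta` and `sigma2` have closed forms from the spatially
#' filtered regression of `(I - lambda W) y` on `(I - lambda W) X`, and the
#' Jacobian `log|I - lambda W|` is evaluated from the (real) eigenvalues of
#' the row-standardized weights, computed once per weights object and
#' cached.  `lambda` is optimised by Brent search on
#' `(1/omega_min, 1/omega_max)` with tolerance 1e-8.  Standard errors come
#' from the asymptotic information matrix; coefficient p-values are
#' two-sided z-tests.
#'
#' Cells flagged isolated in `w` are dropped from the fit (with a warning);
#' `y` and `X` must be aligned with `w$ids`.
#'
#' @param y Numeric response vector.
#' @param X Numeric matrix (or data frame) of predictors, without intercept.
#' @param w A [build_weights()] object over the same cells.
#' @param intercept Include an intercept column (default TRUE).
#' @param lambda Either `NULL` (estimate, the default) or a fixed value
#'   (0 reduces the model to OLS).
#' @return A `sar_fit` object: `beta`, `se_beta`, `z`, `p_value` (named,
#'   incl. intercept), `lambda_sar`, `se_lambda`, `sigma2`, `loglik`,
#'   `loglik_lambda0`, `n`, `vcov_beta`, `residuals` (u = y - X beta),
#'   `filtered_residuals` ((I - lambda W) u).
#' @examples
#' w <- build_weights(0:99, grid_spec(10, 10), "queen")
#' set.seed(1); x <- rnorm(100); y <- 2 * x + rnorm(100)
#' fit <- fit_sar_error(y, cbind(x = x), w)
#' fit$beta[["x"]]
#' @export
fit_sar_error <- function(y, X, w, intercept = TRUE, lambda = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == length(w$ids), nrow(X) == length(y))
  if (any(w$isolated)) {
    warning(sum(w$isolated), " isolated cell(s) dropped from SAR fit")
    keep <- !w$isolated
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    w <- drop_isolated(w)
  }
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- length(y); p <- ncol(X)
  if (n <= p + 2) stop("too few observations (n = ", n, ", p = ", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("rank-deficient design; drop column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]], collapse = ", "))

  W <- w$W
  ev <- weights_eigenvalues(w)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6

  Wy <- as.numeric(W %*% y)
  WX <- as.matrix(W %*% X)

  profile <- function(lam) {
    Ay <- y - lam * Wy
    AX <- X - lam * WX
    fit <- lm.fit(AX, Ay)
    e <- fit$residuals
    s2 <- sum(e^2) / n
    list(beta = fit$coefficients, sigma2 = s2, resid_filtered = e,
         ll = -n / 2 * (log(2 * pi * s2) + 1) + sum(log1p(-lam * ev)))
  }
  conc_ll <- function(lam) profile(lam)$ll

  ll0 <- conc_ll(0)
  if (is.null(lambda)) {
    opt <- optimize(conc_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    lam_hat <- opt$maximum
    ll_hat <- opt$objective
    if (ll_hat < ll0) { lam_hat <- 0; ll_hat <- ll0 }  # guard boundary cases
  } else {
    stopifnot(is.numeric(lambda), lambda > lo, lambda < hi)
    lam_hat <- lambda
    ll_hat <- conc_ll(lambda)
  }
  if (!is.finite(ll_hat))
    stop("SAR likelihood did not converge (non-finite log-likelihood at ",
         "lambda = ", format(lam_hat), ")")

  pr <- profile(lam_hat)
  beta <- pr$beta; s2 <- pr$sigma2
  AX <- X - lam_hat * WX
  XtX <- crossprod(AX)
  vcov_beta <- s2 * solve(XtX)
  se_beta <- sqrt(diag(vcov_beta))

  ## information for (lambda, sigma2); beta block is orthogonal
  WB <- as.matrix(Matrix::solve(Diagonal(n) - lam_hat * W, W))
  I_ll <- sum(WB * t(WB)) + sum(WB^2)
  I_ls <- sum(diag(WB)) / s2
  I_ss <- n / (2 * s2^2)
  det_i <- I_ll * I_ss - I_ls^2
  se_lambda <- if (det_i > 0) sqrt(I_ss / det_i) else NA_real_

  zstat <- beta / se_beta
  pv <- 2 * pnorm(abs(zstat), lower.tail = FALSE)
  u <- as.numeric(y - X %*% beta)

  structure(list(beta = setNames(as.numeric(beta), colnames(X)),
                 se_beta = setNames(as.numeric(se_beta), colnames(X)),
                 z = setNames(as.numeric(zstat), colnames(X)),
                 p_value = setNames(as.numeric(pv), colnames(X)),
                 lambda_sar = lam_hat, se_lambda = se_lambda,
                 sigma2 = s2, loglik = ll_hat, loglik_lambda0 = ll0,
                 n = n, vcov_beta = vcov_beta,
                 residuals = u, filtered_residuals = pr$resid_filtered,
                 lambda_fixed = !is.null(lambda)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR error model (ML): n = %d, lambda = %.4f (se %.4f), logLik = %.2f\n",
              x$n, x$lambda_sar, x$se_lambda, x$loglik))
  tab <- data.frame(estimate = x$beta, se = x$se_beta, z = x$z,
                    p = signif(x$p_value, 3))
  print(tab)
  invisible(x)
}

#' Serialise a SAR fit to JSON
#'
#' @param fit A `sar_fit`.
#' @param path Output path.
#' @export
write_sar_fit <- function(fit, path) {
  jsonlite::write_json(
    list(beta = as.list(fit$beta), se_beta = as.list(fit$se_beta),
         p_value = as.list(fit$p_value), lambda_sar = fit$lambda_sar,
         se_lambda = fit$se_lambda, sigma2 = fit$sigma2,
         loglik = fit$loglik, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
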