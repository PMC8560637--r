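#' Global Moran's I with analytic and permutation inference
#'
#' Computes Moran's I over a spatial weights matrix,
#' `I = (n/S0) * (z' W z)/(z' z)` with `z` the centred values and `S0` the
#' sum of all weights.  The null expectation is `E[I] = -1/(n-1)`.  The
#' analytic p-value uses the normality variance of Cliff & Ord; the
#' permutation p-value shuffles values over cells (seeded) and is computed
#' as `(1 + #{I_perm at least as extreme}) / (n_perm + 1)`.
#'
#' @param values Numeric vector aligned with `w$ids`; must be non-constant.
#' @param w A [build_weights()] object.
#' @param n_perm Number of permutations (>= 99 recommended; default 999).
#' @param alternative `"greater"` (positive autocorrelation, default),
#'   `"less"` or `"two.sided"`.
#' @param seed Integer seed for the permutations.
#' @return A `morans_i` list: `I`, `expectation`, `variance`, `p_analytic`,
#'   `p_permutation`, `n`, `alternative`.
#' @examples
#' w <- build_weights(0:15, grid_spec(4, 4), "rook")
#' morans_i(rnorm(16), w, n_perm = 99, seed = 1)$expectation  # -1/15
#' @export
morans_i <- function(values, w, n_perm = 999, alternative = "greater",
                     seed = 1L) {
  stopifnot(inherits(w, "spatial_weights"),
            length(values) == length(w$ids))
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  if (any(w$isolated)) {
    keep <- !w$isolated
    values <- values[keep]
    w <- drop_isolated(w)
  }
  n <- length(values)
  if (n < 4) stop("need at least 4 non-isolated cells")
  if (sd(values) == 0) stop("constant values: Moran's I undefined")

  W <- w$W
  S0 <- sum(W)
  z <- values - mean(values)
  denom <- sum(z^2)
  I_obs <- (n / S0) * as.numeric(crossprod(z, W %*% z)) / denom
  EI <- -1 / (n - 1)

  Wd <- W + Matrix::t(W)
  S1 <- 0.5 * sum(Wd@x^2)
  rs <- rowSums(W); cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)
  EI2 <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2)
  VI <- EI2 - EI^2
  zsc <- (I_obs - EI) / sqrt(VI)
  p_an <- switch(alternative,
                 greater = pnorm(zsc, lower.tail = FALSE),
                 less = pnorm(zsc),
                 two.sided = 2 * pnorm(abs(zsc), lower.tail = FALSE))

  ## permutation: reuse the sparse triplet form for speed
  T3 <- methods::as(W, "TsparseMatrix")
  ti <- T3@i + 1L; tj <- T3@j + 1L; tw <- T3@x
  set.seed(seed)
  I_perm <- vapply(seq_len(n_perm), function(k) {
    zp <- z[sample.int(n)]
    (n / S0) * sum(tw * zp[ti] * zp[tj]) / denom
  }, 0)
  p_pm <- switch(alternative,
                 greater = (1 + sum(I_perm >= I_obs)) / (n_perm + 1),
                 less = (1 + sum(I_perm <= I_obs)) / (n_perm + 1),
                 two.sided = (1 + sum(abs(I_perm - EI) >= abs(I_obs - EI))) /
                   (n_perm + 1))

  structure(list(I = I_obs, expectation = EI, variance = VI,
                 p_analytic = p_an, p_permutation = p_pm, n = n,
                 n_perm = n_perm, alternative = alternative),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), p_analytic = %.3g, p_perm = %.3g (%s, n = %d)\n",
              x$I, x$expectation, x$p_analytic, x$p_permutation,
              x$alternative, x$n))
  invisible(x)
}
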