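#' Decompose standardized direct, indirect and total effects
#'
#' Given a standardized edge-coefficient matrix `B` (rows = responses,
#' columns = sources), the direct effect of a source on the response is its
#' edge coefficient (0 if the edge is absent); the indirect effect is the
#' sum over all directed paths of length >= 2 of the products of edge
#' coefficients; and the total is their sum.  Both an explicit
#' path-enumeration and the closed form `(I - B)^{-1} - I` are computed and
#' must agree to 1e-12 — a structural identity of linear path models.
#'
#' @param B Square numeric matrix `B[response, source]` of standardized edge
#'   coefficients, with dimnames; must describe a DAG.
#' @param response Name of the terminal response node.
#' @param sources Source nodes (default: all other nodes).
#' @return Data frame with `source`, `direct`, `indirect`, `total`.
#' @examples
#' B <- matrix(0, 3, 3, dimnames = list(c("x","m","y"), c("x","m","y")))
#' B["m","x"] <- 0.5; B["y","m"] <- 0.4; B["y","x"] <- 0.2
#' decompose_effects(B, "y")   # total(x) = 0.2 + 0.5*0.4 = 0.4
#' @export
decompose_effects <- function(B, response, sources = NULL) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B),
            !is.null(rownames(B)), identical(rownames(B), colnames(B)),
            response %in% rownames(B))
  nodes <- rownames(B)
  sources <- sources %||% setdiff(nodes, response)
  ## DAG check: nilpotency of the adjacency pattern
  P <- (B != 0) * 1
  Pk <- P
  for (i in seq_len(nrow(B))) {
    if (sum(Pk) == 0) break
    if (any(diag(Pk) != 0)) stop("coefficient matrix is cyclic")
    Pk <- Pk %*% P
  }
  if (sum(Pk) != 0) stop("coefficient matrix is cyclic")

  total_mat <- solve(diag(nrow(B)) - B) - diag(nrow(B))
  enum_total <- vapply(sources, function(s)
    sum_paths(B, from = s, to = response), 0)
  closed <- total_mat[response, sources]
  if (max(abs(enum_total - closed)) > 1e-12 * max(1, max(abs(closed))))
    stop("path enumeration and matrix inverse disagree; numerical problem")
  direct <- as.numeric(B[response, sources])
  indirect <- as.numeric(closed) - direct
  # total defined as the sum, so the decomposition identity is exact
  data.frame(source = sources, direct = direct, indirect = indirect,
             total = direct + indirect, row.names = NULL,
             stringsAsFactors = FALSE)
}

## Sum of coefficient products over all directed paths from -> to (DFS).
sum_paths <- function(B, from, to) {
  if (from == to) return(1)
  children <- rownames(B)[B[, from] != 0]
  if (!length(children)) return(0)
  sum(vapply(children, function(ch) B[ch, from] * sum_paths(B, ch, to), 0))
}

effect_groups <- function() {
  list(elevation = c("elev_change", "elev_now"),
       temperature = c("t_change", "t_now"),
       historical = c("elev_change", "t_change"),
       present = c("elev_now", "t_now"))
}

#' Standardized effects of every predictor on the log speciation rate
#'
#' Reads the standardized edge coefficients off a fitted path model and
#' returns the direct/indirect/total decomposition for each individual
#' predictor, plus aggregated groups (elevation = change + present
#' elevation; temperature = change + present temperature; historical = both
#' change variables; present = both present-day variables), each group value
#' being the sum of its members' effects.
#'
#' @param path_fit A [fit_path_model()] result.
#' @param response Terminal response node (default `"log_lambda"`).
#' @return An `effect_decomposition` data frame: `term`, `kind`
#'   (`"predictor"`/`"group"`), `direct`, `indirect`, `total`.
#' @export
total_effects <- function(path_fit, response = "log_lambda") {
  stopifnot(inherits(path_fit, "path_fit"))
  B <- fitted_beta_matrix(path_fit)
  eff <- decompose_effects(B, response)
  out <- data.frame(term = eff$source, kind = "predictor",
                    direct = eff$direct, indirect = eff$indirect,
                    total = eff$total, stringsAsFactors = FALSE)
  for (g in names(effect_groups())) {
    members <- intersect(effect_groups()[[g]], eff$source)
    if (!length(members)) next
    i <- match(members, eff$source)
    out <- rbind(out, data.frame(term = g, kind = "group",
                                 direct = sum(eff$direct[i]),
                                 indirect = sum(eff$indirect[i]),
                                 total = sum(eff$total[i]),
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("effect_decomposition", "data.frame")
  attr(out, "response") <- response
  attr(out, "sd_log_lambda") <- path_fit$sd_log_lambda
  out
}

#' Monte-Carlo confidence intervals for path effects
#'
#' Propagates per-equation coefficient uncertainty to the effect
#' decomposition: each equation's coefficients are drawn from their
#' asymptotic multivariate normal distribution (independently across
#' equations, as the component regressions are fitted independently), the
#' decomposition is recomputed per draw, and percentile intervals are
#' attached to each effect.
#'
#' @param path_fit A [fit_path_model()] result.
#' @param n_draws Number of Monte-Carlo draws (default 1000; < 100 warns).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @param response Terminal response node.
#' @return The [total_effects()] data frame with added columns
#'   `<direct|indirect|total>_lo` / `_hi`.
#' @export
effect_uncertainty <- function(path_fit, n_draws = 1000, level = 0.95,
                               seed = 1L, response = "log_lambda") {
  stopifnot(inherits(path_fit, "path_fit"))
  if (n_draws < 100) warning("n_draws < 100 gives unstable intervals")
  point <- total_effects(path_fit, response)
  spec <- path_fit$spec
  set.seed(seed)
  draws_per_eq <- lapply(path_fit$fits, function(f) {
    keep <- setdiff(names(f$beta), "(Intercept)")
    MASS::mvrnorm(n_draws, mu = f$beta, Sigma = f$vcov_beta)[, keep,
                                                             drop = FALSE]
  })
  nodes <- spec$nodes
  samples <- matrix(NA_real_, n_draws, nrow(point),
                    dimnames = list(NULL, paste(point$term, point$kind)))
  direct_s <- indirect_s <- samples
  groups <- effect_groups()
  for (k in seq_len(n_draws)) {
    B <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (r in names(spec$equations))
      B[r, spec$equations[[r]]] <- draws_per_eq[[r]][k, spec$equations[[r]]]
    tot <- solve(diag(length(nodes)) - B) - diag(length(nodes))
    for (i in seq_len(nrow(point))) {
      trm <- point$term[i]
      members <- if (point$kind[i] == "group")
        intersect(groups[[trm]], nodes) else trm
      direct_s[k, i] <- sum(B[response, members])
      samples[k, i] <- sum(tot[response, members])
      indirect_s[k, i] <- samples[k, i] - direct_s[k, i]
    }
  }
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  qt <- qs(samples); qd <- qs(direct_s); qi <- qs(indirect_s)
  point$direct_lo <- qd[1, ]; point$direct_hi <- qd[2, ]
  point$indirect_lo <- qi[1, ]; point$indirect_hi <- qi[2, ]
  point$total_lo <- qt[1, ]; point$total_hi <- qt[2, ]
  attr(point, "n_draws") <- n_draws
  attr(point, "level") <- level
  point
}

#' Percent change in speciation rate per standard deviation of a predictor
#'
#' Converts a standardized effect on the log response into the percent
#' change in the (unlogged) speciation rate produced by a one-s.d. change in
#' the predictor: `100 * (exp(effect * sd_log_lambda) - 1)`, where
#' `sd_log_lambda` is the subset standard deviation of the unstandardized
#' log response.
#'
#' @param effect Standardized effect(s).
#' @param sd_log_lambda Sd of the log response on its natural scale.
#' @return Percent change(s).
#' @examples
#' percent_change_per_sd(0.1, 1)  # 10.517...
#' @export
percent_change_per_sd <- function(effect, sd_log_lambda) {
  100 * (exp(effect * sd_log_lambda) - 1)
}

#' Flag effects below a display threshold
#'
#' Following the convention of showing only effects that change the response
#' by at least a given percentage per standard deviation of the predictor,
#' adds `percent_per_sd` and a logical `suppressed` column; nothing is
#' deleted from the table.
#'
#' @param effects An `effect_decomposition` (point or with CIs).
#' @param sd_log_lambda Sd of the unstandardized log response.
#' @param threshold_pct Display threshold in percent (default 5; 0 retains
#'   everything).
#' @return The input with `percent_per_sd` and `suppressed` columns.
#' @export
display_filter <- function(effects, sd_log_lambda, threshold_pct = 5) {
  stopifnot(is.data.frame(effects), "total" %in% names(effects))
  effects$percent_per_sd <- percent_change_per_sd(effects$total,
                                                  sd_log_lambda)
  effects$suppressed <- abs(effects$percent_per_sd) < threshold_pct
  effects
}
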