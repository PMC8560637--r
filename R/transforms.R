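#' Transform cell-table variables for model fitting
#'
#' Applies the analysis transforms within the subset being fitted: the
#' response is the (already log) speciation rate, standardized for effect
#' reporting; present-day elevation is log-transformed (with an offset rule
#' for non-positive onshore values, see Details) and all predictors are then
#' centred to mean 0 and scaled to sd 1.  Transform parameters are returned
#' so values can be back-converted.
#'
#' If any present-day elevation in the subset is `<= 0` (coastal or
#' below-sea-level land), the whole subset is shifted before the log:
#' `log(elev_now - min(elev_now) + 1)`; the offset used is recorded.
#'
#' @param cells A `cell_table` (or any data frame with `elev_now`,
#'   `elev_change`, `t_now`, `t_change`, `log_lambda`).
#' @param subset Optional logical/integer index selecting the rows to fit
#'   (e.g. the uplift cells).
#' @param log_elev Log-transform present elevation (default TRUE).
#' @return A `model_frame` list: `data` (standardized variables, response
#'   `log_lambda` standardized), `centers`, `scales`, `sd_log_lambda`
#'   (unstandardized subset sd of the log response), `elev_offset`,
#'   `cell_id`.
#' @export
transform_variables <- function(cells, subset = NULL, log_elev = TRUE) {
  need <- c("elev_now", "elev_change", "t_now", "t_change", "log_lambda")
  stopifnot(all(need %in% names(cells)))
  d <- as.data.frame(cells)
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  if (!nrow(d)) stop("empty subset")

  elev_offset <- 0
  if (log_elev) {
    if (any(d$elev_now <= 0)) {
      elev_offset <- -min(d$elev_now) + 1
      message("non-positive present elevation in subset; applying offset ",
              format(elev_offset))
    }
    d$elev_now <- log(d$elev_now + elev_offset)
  }

  vars <- c("elev_change", "t_change", "elev_now", "t_now", "log_lambda")
  centers <- vapply(d[vars], mean, 0)
  scales <- vapply(d[vars], sd, 0)
  degenerate <- names(scales)[!is.finite(scales) | scales == 0]
  if (length(degenerate))
    stop("zero-variance variable(s) in subset: ",
         paste(degenerate, collapse = ", "))
  z <- as.data.frame(mapply(function(x, m, s) (x - m) / s,
                            d[vars], centers, scales, SIMPLIFY = FALSE))
  structure(list(data = z, centers = centers, scales = scales,
                 sd_log_lambda = scales[["log_lambda"]],
                 elev_offset = elev_offset, log_elev = log_elev,
                 cell_id = d$cell_id %||% seq_len(nrow(d))),
            class = "model_frame")
}

#' @rdname transform_variables
#' @param mf A `model_frame`.
#' @param var Variable name to back-transform.
#' @param z Standardized values.
#' @return `back_transform` returns values on the original scale.
#' @export
back_transform <- function(mf, var, z) {
  stopifnot(inherits(mf, "model_frame"), var %in% names(mf$centers))
  x <- z * mf$scales[[var]] + mf$centers[[var]]
  if (var == "elev_now" && mf$log_elev) x <- exp(x) - mf$elev_offset
  x
}

#' Pairwise Spearman collinearity screen of model predictors
#'
#' Computes all pairwise Spearman rank correlations among predictors and
#' flags the screen as failed when any `|rho|` reaches the threshold
#' (default 0.6).  Failure is a flag, not an error: fits may proceed, but
#' the flag should be reported.
#'
#' @param x Data frame or matrix of predictors (>= 2 columns).
#' @param threshold Absolute-rho failure threshold.
#' @return List with `rho` (symmetric matrix), `max_abs_rho`, `pass`
#'   (logical), `threshold`, and `pairs` (data frame of pairs ordered by
#'   `|rho|`).
#' @export
collinearity_screen <- function(x, threshold = 0.6) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2)
  rho <- cor(x, method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- data.frame(var1 = colnames(rho)[ut[, 1]],
                      var2 = colnames(rho)[ut[, 2]],
                      rho = rho[ut])
  pairs <- pairs[order(-abs(pairs$rho)), ]
  rownames(pairs) <- NULL
  list(rho = rho, max_abs_rho = max(abs(pairs$rho)),
       pass = max(abs(pairs$rho)) < threshold, threshold = threshold,
       pairs = pairs)
}
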