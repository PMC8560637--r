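#' Specify a piecewise path model
#'
#' A path model is an ordered list of component regressions over a DAG,
#' written as formula-like strings `"response ~ pred1 + pred2"`.  Exogenous
#' nodes appear only on right-hand sides.  The specification is validated to
#' be acyclic, with every predictor a node of the graph; bidirectional or
#' feedback links are rejected.
#'
#' @param equations Character vector of `"response ~ predictors"` strings.
#' @return A `path_model_spec`: list with `equations` (named list of
#'   predictor vectors), `nodes` (topologically ordered), `edges`
#'   (data frame `from`, `to`).
#' @examples
#' spec <- path_model_spec(c("m ~ x", "y ~ x + m"))
#' spec$nodes
#' @export
path_model_spec <- function(equations) {
  stopifnot(is.character(equations), length(equations) >= 1)
  eqs <- list()
  for (s in equations) {
    parts <- strsplit(s, "~", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed equation: ", s)
    resp <- trimws(parts[1])
    preds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    preds <- preds[nzchar(preds)]
    if (!nzchar(resp) || !length(preds)) stop("malformed equation: ", s)
    if (resp %in% preds) stop("self-loop in equation: ", s)
    if (resp %in% names(eqs)) stop("duplicate response: ", resp)
    eqs[[resp]] <- preds
  }
  nodes <- union(unlist(eqs), names(eqs))
  edges <- do.call(rbind, lapply(names(eqs), function(r)
    data.frame(from = eqs[[r]], to = r, stringsAsFactors = FALSE)))
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate edge in specification")
  both <- merge(edges, setNames(edges, c("to", "from")))
  if (nrow(both))
    stop("bidirectional link(s) not allowed: ",
         paste(unique(pmin(both$from, both$to)), collapse = ", "))
  order <- topo_sort(nodes, edges)
  if (is.null(order)) stop("specification is cyclic")
  structure(list(equations = eqs, nodes = order, edges = edges),
            class = "path_model_spec")
}

topo_sort <- function(nodes, edges) {
  indeg <- setNames(rep(0L, length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0])  # lexicographic tie-break
  while (length(avail)) {
    nd <- avail[1]; avail <- avail[-1]
    out <- c(out, nd)
    ch <- edges$to[edges$from == nd]
    for (c2 in ch) {
      indeg[c2] <- indeg[c2] - 1L
      if (indeg[c2] == 0L) avail <- sort(c(avail, c2))
    }
  }
  if (length(out) != length(nodes)) return(NULL)
  out
}

#' Default path model of the topographic-speciation analysis
#'
#' Encodes the hypothesised causal structure: elevation change drives
#' present elevation, temperature change and (directly) present temperature;
#' temperature change and present elevation also drive present temperature;
#' and all four abiotic variables drive the log speciation rate.  The
#' `elev_change -> t_now` link is the one a missing-path test adds to the
#' a-priori structure; drop it with `with_ec_tnow_link = FALSE`.
#'
#' @param with_ec_tnow_link Include the direct
#'   `elev_change -> t_now` edge (default TRUE).
#' @return A [path_model_spec()].
#' @export
default_path_spec <- function(with_ec_tnow_link = TRUE) {
  tn <- if (with_ec_tnow_link) "t_now ~ elev_now + t_change + elev_change"
        else "t_now ~ elev_now + t_change"
  path_model_spec(c(
    "elev_now ~ elev_change",
    "t_change ~ elev_change",
    tn,
    "log_lambda ~ elev_change + t_change + elev_now + t_now"))
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("path_model_spec with", length(x$equations), "equations:\n")
  for (r in names(x$equations))
    cat("  ", r, "~", paste(x$equations[[r]], collapse = " + "), "\n")
  invisible(x)
}

spec_adjacent <- function(spec, a, b) {
  any(spec$edges$from == a & spec$edges$to == b) ||
    any(spec$edges$from == b & spec$edges$to == a)
}

## Shipley-style union basis set: for every non-adjacent ordered pair
## (u earlier, v later in topological order), claim v _||_ u | pa(u) U pa(v).
basis_set <- function(spec) {
  nodes <- spec$nodes
  claims <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    u <- nodes[i]; v <- nodes[j]
    if (spec_adjacent(spec, u, v)) next
    cond <- setdiff(union(spec$equations[[u]] %||% character(0),
                          spec$equations[[v]] %||% character(0)),
                    c(u, v))
    claims[[length(claims) + 1]] <- list(u = u, v = v, conditioning = cond)
  }
  claims
}
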