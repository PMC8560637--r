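#' Equal-splits measure for tips of a dated phylogeny
#'
#' The equal-splits (ES) measure of a tip is the sum of the branch lengths on
#' its root-to-tip path, with each successive branch moving rootward from the
#' tip down-weighted by a factor of one half: `ES = sum_j l_j * (1/2)^(j-1)`,
#' where `l_1` is the terminal branch.  Branches closer to the present carry
#' more weight, so short terminal branches (recent splits) give small ES.
#' A root edge, if present, is not part of any tip-to-root path and is
#' ignored.
#'
#' Implemented as a single pre-order pass: the discounted rootward
#' contribution satisfies `g(child) = l(edge) + g(parent)/2` with
#' `g(root) = 0`, and `ES(tip) = g(tip)`.  Polytomies are allowed: the depth
#' index counts edges on the path regardless of node degree (such trees are
#' flagged via the `polytomies` attribute).
#'
#' @param phy A rooted `phylo` tree with branch lengths (Myr).
#' @param tips Character vector of tip labels (default: all tips).
#' @return Named numeric vector of ES values (Myr) for `tips`, with attribute
#'   `polytomies` (logical).
#' @seealso [dr_statistic()] for the inverse, the DR tip speciation rate.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' equal_splits(tr)   # 1.5 for every tip
#' @export
equal_splits <- function(phy, tips = phy$tip.label) {
  check_phylo(phy)
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown))
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "))
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
  ntip <- length(phy$tip.label)
  g <- numeric(ntip + phy$Nnode)
  parent <- phy$edge[, 1]; child <- phy$edge[, 2]
  for (k in seq_along(parent))
    g[child[k]] <- phy$edge.length[k] + g[parent[k]] / 2
  es <- setNames(g[seq_len(ntip)], phy$tip.label)[tips]
  if (any(es <= 0)) stop("non-positive equal-splits value; check branch lengths")
  attr(es, "polytomies") <- !ape::is.binary(phy)
  es
}

#' DR tip speciation-rate statistic
#'
#' Computes the DR statistic for every tip: the inverse of the equal-splits
#' measure, in events/lineage/Myr.  Under a pure-birth process the mean DR
#' across tips estimates the birth rate.
#'
#' @param phy A rooted `phylo` tree with branch lengths in Myr.
#' @param tree_id Optional identifier recorded in the output metadata.
#' @return A `tip_rates` data frame with columns `species_id`, `lambda` and
#'   `statistic`, and attributes `tree_id` and `polytomies`.
#' @examples
#' tr <- ape::read.tree(text = "(A:5,B:5);")
#' dr_statistic(tr)$lambda  # 0.2, 0.2
#' @export
dr_statistic <- function(phy, tree_id = NA_character_) {
  es <- equal_splits(phy)
  out <- data.frame(species_id = names(es), lambda = 1 / as.numeric(es),
                    statistic = "lambda_DR", stringsAsFactors = FALSE)
  attr(out, "tree_id") <- tree_id
  attr(out, "polytomies") <- attr(es, "polytomies")
  class(out) <- c("tip_rates", "data.frame")
  out
}

check_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  term <- phy$edge[, 2] <= length(phy$tip.label)
  if (any(phy$edge.length[term] == 0))
    stop("zero-length terminal branch(es): ",
         paste(phy$tip.label[phy$edge[term, 2][phy$edge.length[term] == 0]],
               collapse = ", "))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  invisible(TRUE)
}

#' Read a rooted, dated phylogeny from a Newick file
#'
#' @param path Path to a Newick file (branch lengths required).
#' @return A validated `phylo` object.
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  if (inherits(phy, "multiPhylo"))
    stop("file contains multiple trees; expected one: ", path)
  check_phylo(phy)
  phy
}

#' Read or write an externally computed tip-rate table
#'
#' Admits speciation rates computed elsewhere (any per-tip rate column, for
#' example from a rate-heterogeneous Bayesian analysis) in a TSV with columns
#' `species_id`, `lambda` and optionally `statistic`.
#'
#' @param path File path.
#' @param rates A `tip_rates` data frame (for writing).
#' @return `load_external_rates` returns a `tip_rates` data frame.
#' @export
load_external_rates <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "lambda") %in% names(d)))
    stop("rate table needs columns species_id and lambda: ", path)
  if (anyDuplicated(d$species_id))
    stop("duplicate species in rate table: ",
         paste(unique(d$species_id[duplicated(d$species_id)]), collapse = ", "))
  bad <- !is.finite(d$lambda) | d$lambda <= 0
  if (any(bad))
    stop("non-positive or missing rate for: ",
         paste(d$species_id[bad], collapse = ", "))
  if (is.null(d$statistic)) d$statistic <- "external"
  d <- d[, c("species_id", "lambda", "statistic")]
  class(d) <- c("tip_rates", "data.frame")
  d
}

#' @rdname load_external_rates
#' @export
write_tip_rates <- function(rates, path) {
  stopifnot(all(c("species_id", "lambda") %in% names(rates)))
  write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
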