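#' Simulate a dated birth-death phylogeny of extant species
#'
#' Simulates a rooted, binary, ultrametric tree with exactly `n_tips` extant
#' tips under a constant-rate birth-death process (branch lengths in Myr),
#' conditioning on the number of surviving tips so extinct lineages never
#' appear in the output.  Tips are labelled `sp1 ... spN`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return An [ape::phylo] object.
#' @examples
#' tr <- simulate_tree(sim_config(n_tips = 10, seed = 3))
#' ape::is.ultrametric(tr)
#' @export
simulate_tree <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  tr <- ape::rphylo(config$n_tips, birth = config$birth_rate,
                    death = config$death_rate, fossils = FALSE)
  tr$tip.label <- paste0("sp", seq_len(config$n_tips))
  tr
}
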