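#' Configure an end-to-end pipeline run
#'
#' Exactly one of `sim` (a [sim_config()] for a synthetic world) or `inputs`
#' (paths to real data) must be supplied.  Real inputs are a named list with
#' `tree` (Newick), `ranges` (TSV: `species_id`, `cell_id`, optional
#' `taxon_group`), and four ESRI ASCII rasters `elev_now`, `elev_past`,
#' `t_now`, `t_past` pre-projected to the grid's equal-area frame; `rates`
#' (TSV) optionally overrides tree-derived DR rates.
#'
#' @param sim A [sim_config()], or NULL.
#' @param inputs Named list of input paths, or NULL.
#' @param grid A [grid_spec()]; required for real inputs (for `sim` it is
#'   derived from the config).
#' @param weights_scheme Neighbour scheme for [build_weights()].
#' @param subsets Cell subsets to fit: any of `"uplift"`, `"erosion"`,
#'   `"all"`.
#' @param required_groups Taxon groups that must all occur in a retained
#'   cell (NULL = no group filter).
#' @param rate_column Assemblage mean used as the response; see
#'   [build_cell_table()].
#' @param spec Path model ([default_path_spec()] by default).
#' @param threshold_pct Display threshold for [display_filter()].
#' @param n_draws Monte-Carlo draws for effect CIs.
#' @param moran_perm Permutations for the residual Moran test.
#' @param seed Integer master seed (mandatory; all stages derive from it).
#' @param out_dir Output directory, or NULL to skip writing artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, inputs = NULL, grid = NULL,
                       weights_scheme = "queen",
                       subsets = c("uplift", "erosion", "all"),
                       required_groups = NULL,
                       rate_column = "weighted_geometric_mean_lambda",
                       spec = default_path_spec(),
                       threshold_pct = 5, n_draws = 1000, moran_perm = 999,
                       seed = 1L, out_dir = NULL) {
  if (is.null(sim) == is.null(inputs))
    stop("provide exactly one of 'sim' or 'inputs'")
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    grid <- grid_spec(sim$grid_rows, sim$grid_cols, sim$cell_size)
  } else {
    need <- c("tree", "ranges", "elev_now", "elev_past", "t_now", "t_past")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in))
      stop("missing input path(s): ", paste(missing_in, collapse = ", "))
    if (is.null(grid)) stop("grid required for real inputs")
  }
  subsets <- match.arg(subsets, c("uplift", "erosion", "all"),
                       several.ok = TRUE)
  structure(list(sim = sim, inputs = inputs, grid = grid,
                 weights_scheme = weights_scheme, subsets = subsets,
                 required_groups = required_groups,
                 rate_column = rate_column, spec = spec,
                 threshold_pct = threshold_pct, n_draws = n_draws,
                 moran_perm = moran_perm, seed = as.integer(seed),
                 out_dir = out_dir), class = "run_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    world <- simulate_world(config$sim, seed = config$seed)
    list(tree = world$tree, ranges = world$ranges,
         rates = world$tip_rates, layers = world$layers,
         grid = world$grid, truth = world$truth)
  } else {
    inp <- config$inputs
    layers <- list(
      elev_now = aggregate_raster(read_ascii_grid(inp$elev_now),
                                  config$grid, "elev_now", "m"),
      elev_past = aggregate_raster(read_ascii_grid(inp$elev_past),
                                   config$grid, "elev_past", "m"),
      t_now = aggregate_raster(read_ascii_grid(inp$t_now),
                               config$grid, "t_now", "degC"),
      t_past = aggregate_raster(read_ascii_grid(inp$t_past),
                                config$grid, "t_past", "degC"))
    tree <- read_newick(inp$tree)
    rates <- if (!is.null(inp$rates)) load_external_rates(inp$rates)
             else dr_statistic(tree, tree_id = basename(inp$tree))
    list(tree = tree, ranges = read_ranges(inp$ranges, config$grid),
         rates = rates, layers = layers, grid = config$grid, truth = NULL)
  }
}

analyse_inputs <- function(inp, config) {
  elev_change <- change_layer(inp$layers$elev_now, inp$layers$elev_past)
  t_change <- change_layer(inp$layers$t_now, inp$layers$t_past)
  sub <- discard_submerged(inp$layers$elev_past)

  cell_rates <- weighted_cell_rates(inp$ranges, inp$rates)
  keep <- intersect(cell_rates$cell_id, sub$retained)
  if (!is.null(config$required_groups))
    keep <- intersect(keep, filter_cells(inp$ranges, config$required_groups))
  cells <- build_cell_table(cell_rates, inp$layers$elev_now, elev_change,
                            inp$layers$t_now, t_change, cells = keep,
                            rate_column = config$rate_column)
  counts <- list(n_species = length(unique(inp$ranges$species_id)),
                 n_occupied_cells = nrow(cell_rates),
                 n_retained_cells = nrow(cells),
                 fraction_submerged = sub$fraction_discarded,
                 n_uplift = sum(cells$class == "uplift"),
                 n_erosion = sum(cells$class == "erosion"))

  results <- list()
  for (s in config$subsets) {
    idx <- if (s == "all") seq_len(nrow(cells)) else which(cells$class == s)
    if (length(idx) < 20) {
      warning("subset '", s, "' has only ", length(idx),
              " cells; skipping fit")
      next
    }
    mf <- transform_variables(cells, subset = idx)
    screen <- collinearity_screen(
      mf$data[setdiff(names(mf$data), "log_lambda")])
    w <- build_weights(cells$cell_id[idx], inp$grid, config$weights_scheme)
    if (any(w$isolated)) {
      keep_nb <- !w$isolated
      mf$data <- mf$data[keep_nb, , drop = FALSE]
      mf$cell_id <- mf$cell_id[keep_nb]
      message(sum(w$isolated), " isolated cell(s) dropped in subset ", s)
      w <- drop_isolated(w)
    }
    ols <- fit_sar_error(mf$data$log_lambda,
                         as.matrix(mf$data[config$spec$equations$log_lambda]),
                         w, lambda = 0)
    moran <- morans_i(ols$residuals, w, n_perm = config$moran_perm,
                      seed = config$seed + 2L)
    pf <- fit_path_model(config$spec, mf, w)
    ds <- dsep_test(config$spec, mf, w)
    eff <- effect_uncertainty(pf, n_draws = config$n_draws,
                              seed = config$seed + 3L)
    eff <- display_filter(eff, mf$sd_log_lambda, config$threshold_pct)
    sar_moran <- morans_i(pf$fits$log_lambda$filtered_residuals, w,
                          n_perm = config$moran_perm,
                          seed = config$seed + 2L)
    results[[s]] <- list(model_frame = mf, weights = w, screen = screen,
                         moran_ols = moran, moran_sar = sar_moran,
                         path_fit = pf, dsep = ds, effects = eff,
                         n_cells = nrow(mf$data))
  }
  list(cells = cells, cell_rates = cell_rates, counts = counts,
       subsets = results,
       layers = c(inp$layers, list(elev_change = elev_change,
                                   t_change = t_change)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — inputs (simulated or read from disk), tip
#' rates, assemblage grid, change layers and cell filters, per-subset
#' transforms, spatial weights, residual Moran diagnostics, SAR-error path
#' model, d-separation test, and effect decomposition with Monte-Carlo CIs —
#' and optionally writes every intermediate artifact plus a manifest.
#' Rerunning with an identical config reproduces all numeric outputs.
#'
#' @param config A [run_config()].
#' @return A `pipeline_run` list: `cells`, `cell_rates`, `counts`, `subsets`
#'   (per-subset fits, diagnostics and effects), `layers`, `truth` (synthetic
#'   mode only), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- pipeline_inputs(config)
  res <- analyse_inputs(inp, config)
  res$truth <- inp$truth
  res$tree <- inp$tree
  res$ranges <- inp$ranges
  res$tip_rates <- inp$rates

  manifest <- list(
    package = "topospec",
    version = as.character(utils::packageVersion("topospec")),
    seed = config$seed,
    mode = if (is.null(config$sim)) "real" else "synthetic",
    weights_scheme = config$weights_scheme,
    rate_column = config$rate_column,
    counts = res$counts,
    subsets = lapply(res$subsets, function(r) list(
      n_cells = r$n_cells,
      moran_i_ols = r$moran_ols$I,
      sar_lambda = r$path_fit$fits$log_lambda$lambda_sar,
      fishers_C = r$dsep$fishers_C, p_C = r$dsep$p_C)))

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tip_rates(inp$rates, file.path(dir, "tip_rates.tsv"))
    write_cell_rates(res$cell_rates, file.path(dir, "cell_rates.tsv"))
    write.table(res$cells, file.path(dir, "cell_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (s in names(res$subsets)) {
      r <- res$subsets[[s]]
      write.table(coefficient_table(r$path_fit),
                  file.path(dir, paste0("coefficients_", s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(r$effects, file.path(dir, paste0("effects_", s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_dsep_report(r$dsep, file.path(dir, paste0("dsep_", s, ".json")))
      jsonlite::write_json(
        list(I = r$moran_ols$I, expectation = r$moran_ols$expectation,
             p_permutation = r$moran_ols$p_permutation,
             I_sar_filtered = r$moran_sar$I),
        file.path(dir, paste0("moran_", s, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    cfg_path <- file.path(dir, "config.json")
    jsonlite::write_json(config_digestible(config), cfg_path,
                         auto_unbox = TRUE, digits = NA)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  res
}

coefficient_table <- function(path_fit) {
  do.call(rbind, lapply(names(path_fit$fits), function(r) {
    f <- path_fit$fits[[r]]
    terms <- setdiff(names(f$beta), "(Intercept)")
    data.frame(response = r, predictor = terms,
               estimate = unname(f$beta[terms]),
               se = unname(f$se_beta[terms]),
               p_value = unname(f$p_value[terms]),
               lambda_sar = f$lambda_sar, n = f$n,
               stringsAsFactors = FALSE)
  }))
}

config_digestible <- function(config) {
  list(sim = if (!is.null(config$sim)) unclass(config$sim),
       inputs = config$inputs, grid = unclass(config$grid),
       weights_scheme = config$weights_scheme, subsets = config$subsets,
       required_groups = config$required_groups,
       rate_column = config$rate_column,
       equations = lapply(config$spec$equations, paste, collapse = " + "),
       threshold_pct = config$threshold_pct, n_draws = config$n_draws,
       moran_perm = config$moran_perm, seed = config$seed)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", x$counts$n_retained_cells, "cells (",
      x$counts$n_uplift, "uplift /", x$counts$n_erosion, "erosion ),",
      x$counts$n_species, "species\n")
  for (s in names(x$subsets)) {
    r <- x$subsets[[s]]
    tot <- r$effects$total[r$effects$term == "elev_change"]
    cat(sprintf("  %s: n = %d, Moran's I (OLS resid) = %.3f, total effect of elev_change = %.3f\n",
                s, r$n_cells, r$moran_ols$I, tot))
  }
  invisible(x)
}

#' Rerun the analysis over a directory of replicate trees
#'
#' Reruns rate estimation and all downstream stages once per tree (Newick
#' files in `tree_dir`), holding ranges and landscape fixed, and summarises
#' the spread of every effect across trees — the robustness check against
#' phylogenetic (topological and branch-length) uncertainty.  Tree-derived
#' DR rates are used for every replicate.
#'
#' @param config A [run_config()].
#' @param tree_dir Directory containing >= 2 Newick files (`.nwk`, `.tre`,
#'   `.newick`, `.txt`).
#' @param reference_run Optional [run_pipeline()] result (e.g. from a
#'   consensus tree); the summary then records whether each of its effects
#'   falls inside the replicate envelope.
#' @param subsets Subsets to summarise (default: `config$subsets`).
#' @return A `tree_replicates` list: `per_tree` (long data frame of total
#'   effects), `summary` (per subset and term: min/max/median/2.5%/97.5%),
#'   `reference_within_envelope` (if a reference run was given).
#' @export
replicate_over_trees <- function(config, tree_dir, reference_run = NULL,
                                 subsets = NULL) {
  stopifnot(inherits(config, "run_config"))
  files <- sort(list.files(tree_dir, pattern = "\\.(nwk|tre|newick|txt)$",
                           full.names = TRUE))
  if (length(files) < 2)
    stop("need at least 2 tree files in ", tree_dir)
  subsets <- subsets %||% config$subsets
  inp <- pipeline_inputs(config)

  per_tree <- do.call(rbind, lapply(files, function(f) {
    tree <- read_newick(f)
    inp$rates <- dr_statistic(tree, tree_id = basename(f))
    drop <- setdiff(unique(inp$ranges$species_id), tree$tip.label)
    res <- suppressWarnings(analyse_inputs(inp, config))
    do.call(rbind, lapply(intersect(subsets, names(res$subsets)),
                          function(s) {
      eff <- total_effects(res$subsets[[s]]$path_fit)
      data.frame(tree = basename(f), subset = s, term = eff$term,
                 total = eff$total, n_dropped_species = length(drop),
                 stringsAsFactors = FALSE)
    }))
  }))

  smry <- do.call(rbind, lapply(split(per_tree,
                                      per_tree[c("subset", "term")]),
                                function(d) {
    if (!nrow(d)) return(NULL)
    q <- quantile(d$total, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(subset = d$subset[1], term = d$term[1], n_trees = nrow(d),
               min = min(d$total), q2.5 = q[1], median = q[2], q97.5 = q[3],
               max = max(d$total), stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL

  out <- list(per_tree = per_tree, summary = smry, n_trees = length(files))
  if (!is.null(reference_run)) {
    ref <- do.call(rbind, lapply(intersect(subsets,
                                           names(reference_run$subsets)),
                                 function(s) {
      eff <- total_effects(reference_run$subsets[[s]]$path_fit)
      data.frame(subset = s, term = eff$term, ref_total = eff$total,
                 stringsAsFactors = FALSE)
    }))
    m <- merge(smry, ref)
    m$within_envelope <- m$ref_total >= m$min & m$ref_total <= m$max
    out$reference_within_envelope <- m
  }
  class(out) <- "tree_replicates"
  out
}
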