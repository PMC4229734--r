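#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulation: matrix dimensions, planted gene-class
#' proportions, the abundance dynamic range, planted interaction propensities,
#' and replicate/dropout behaviour. Defaults emulate the broad marginals of a
#' fly-scale compendium: 15 adult-tissue or 30 developmental-stage conditions,
#' an abundance dynamic range of four orders of magnitude, class proportions
#' matching genome-scale tissue classifications (roughly 31% ubiquitous, 46%
#' non-ubiquitous non-specific, 22% specific), an 8-fold excess of
#' ubiquitous-ubiquitous protein interactions, a 5-fold specific-ubiquitous
#' excess, a 5-fold depletion of specific-specific interactions, and a 3-fold
#' excess of matched specific TF to same-condition-specific-target regulatory
#' edges.
#'
#' The PPI fold parameters are *target fold differences as measured by*
#' [fold_difference()] against size-matched random sets, not raw propensity
#' multipliers; [simulate_ppi_network()] converts them internally (see the
#' methods vignette).
#'
#' @param n_genes Number of genes to simulate.
#' @param tissue_conditions,stage_conditions Number of conditions in the two
#'   regimes.
#' @param class_proportions Named or ordered length-3 numeric: proportions of
#'   (ubiquitous, NUNS, specific) genes; must sum to 1.
#' @param dynamic_range_decades Log10 span of per-gene maximal abundances.
#' @param fold_uu,fold_ss,fold_us Planted fold differences for
#'   ubiquitous-ubiquitous, specific-specific, and ubiquitous-specific edge
#'   counts relative to random sets (1 = no planted structure).
#' @param pdi_matched_fold Oversampling factor for specific-TF to
#'   same-condition-specific-target regulatory edges.
#' @param n_tf Number of transcription factors in the regulatory network.
#' @param mean_degree Mean PPI degree.
#' @param pdi_out_degree Mean TF out-degree in the regulatory network.
#' @param degree_exponent Pareto tail exponent of the per-gene activity
#'   weights driving degree heterogeneity (larger = lighter tail).
#' @param replicate_count Number of replicates in raw replicate tables.
#' @param dropout_rate Per-replicate probability of an "absent" call.
#' @param n_terms Number of annotation terms generated.
#' @param term_size Length-2 integer range of annotation-term sizes.
#' @param planted_term_fold Oversampling of condition-specific genes in
#'   planted annotation terms.
#' @param seed Integer seed; fully determines all generator output.
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$class_proportions
#' @export
sim_config <- function(n_genes = 2000,
                       tissue_conditions = 15,
                       stage_conditions = 30,
                       class_proportions = c(
                         ubiquitous = 3960 / 12628,
                         nuns = 5830 / 12628,
                         specific = 2838 / 12628
                       ),
                       dynamic_range_decades = 4,
                       fold_uu = 8,
                       fold_ss = 1 / 5,
                       fold_us = 5,
                       pdi_matched_fold = 3,
                       n_tf = 50,
                       mean_degree = 10,
                       pdi_out_degree = 100,
                       degree_exponent = 2.5,
                       replicate_count = 4,
                       dropout_rate = 0.05,
                       n_terms = 40,
                       term_size = c(10L, 80L),
                       planted_term_fold = 4,
                       seed = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    tissue_conditions = as.integer(tissue_conditions),
    stage_conditions = as.integer(stage_conditions),
    class_proportions = class_proportions,
    dynamic_range_decades = dynamic_range_decades,
    fold_uu = fold_uu,
    fold_ss = fold_ss,
    fold_us = fold_us,
    pdi_matched_fold = pdi_matched_fold,
    n_tf = as.integer(n_tf),
    mean_degree = mean_degree,
    pdi_out_degree = pdi_out_degree,
    degree_exponent = degree_exponent,
    replicate_count = as.integer(replicate_count),
    dropout_rate = dropout_rate,
    n_terms = as.integer(n_terms),
    term_size = as.integer(term_size),
    planted_term_fold = planted_term_fold,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0)) {
    stop_config("class_proportions must be 3 nonnegative finite fractions")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_config("class_proportions must sum to 1 (got %.12f)", sum(p))
  }
  if (cfg$n_genes < 3L) stop_config("n_genes must be at least 3")
  if (cfg$tissue_conditions < 2L || cfg$stage_conditions < 2L) {
    stop_config("condition counts must be at least 2")
  }
  folds <- c(cfg$fold_uu, cfg$fold_ss, cfg$fold_us, cfg$pdi_matched_fold)
  if (any(!is.finite(folds)) || any(folds < 0)) {
    stop_config("fold multipliers must be nonnegative and finite")
  }
  if (cfg$dynamic_range_decades <= 0) {
    stop_config("dynamic_range_decades must be positive")
  }
  if (cfg$mean_degree <= 0 || cfg$mean_degree >= cfg$n_genes - 1) {
    stop_config(
      "mean_degree %.1f infeasible for %d genes", cfg$mean_degree, cfg$n_genes
    )
  }
  if (cfg$n_tf > cfg$n_genes) stop_config("n_tf cannot exceed n_genes")
  if (cfg$replicate_count < 2L) stop_config("replicate_count must be >= 2")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    stop_config("dropout_rate must be a probability")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d genes, %d tissue / %d stage conditions\n",
    x$n_genes, x$tissue_conditions, x$stage_conditions
  ))
  cat(sprintf(
    "  class proportions (ubiq/NUNS/specific): %.3f / %.3f / %.3f\n",
    x$class_proportions[1], x$class_proportions[2], x$class_proportions[3]
  ))
  cat(sprintf(
    "  planted folds uu/ss/us: %.2f / %.2f / %.2f; PDI matched fold %.2f\n",
    x$fold_uu, x$fold_ss, x$fold_us, x$pdi_matched_fold
  ))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}
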