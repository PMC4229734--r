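# End-to-end orchestration: simulate (or accept) inputs, normalize and
# classify expression, run group statistics, pmax-filter subnetworks, score
# enrichment, and cluster contexts.

#' Pipeline configuration
#'
#' Collects every stage parameter. Inputs may be supplied directly
#' (`expression`, `ppi`, `pdi`, `annotations`); any left `NULL` is simulated
#' from `sim` (a [sim_config()]), so the default configuration runs fully
#' synthetically. The master `seed` drives every stochastic stage through
#' derived per-stage streams.
#'
#' @param sim A [sim_config()] for the synthetic inputs.
#' @param expression Optional wide expression tibble.
#' @param ppi Optional undirected `ppi_network`.
#' @param pdi Optional directed `ppi_network` (may have zero rows to skip
#'   the regulatory-network stages).
#' @param annotations Optional [annotation_set()].
#' @param regime `"tissue"` or `"stage"`.
#' @param pmax_thresholds pmax cut-offs for the filter sweep.
#' @param n_trials Random sets per fold-difference test.
#' @param n_sims Simulations per Monte-Carlo p-value.
#' @param ppi_ci,pdi_ci Binomial CI levels for the PPI and regulatory tests.
#' @param pdi_nets Null networks for the regulatory degree-preserving test.
#' @param n_contexts Number of focal conditions carried through the filter
#'   and enrichment stages (the conditions with most specific genes).
#' @param correction Multiple-testing correction for enrichment.
#' @param seed Master seed (required).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            expression = NULL, ppi = NULL, pdi = NULL,
                            annotations = NULL,
                            regime = c("tissue", "stage"),
                            pmax_thresholds = c(25, 45, 50, 65, 75, 85),
                            n_trials = 1000, n_sims = 10000,
                            ppi_ci = 0.9999, pdi_ci = 0.95,
                            pdi_nets = 1000, n_contexts = 3,
                            correction = c("bonferroni", "bh"),
                            seed) {
  if (missing(seed) || is.null(seed)) {
    stop_config("a master seed is required")
  }
  structure(
    list(
      sim = sim, expression = expression, ppi = ppi, pdi = pdi,
      annotations = annotations, regime = match.arg(regime),
      pmax_thresholds = sort(pmax_thresholds),
      n_trials = n_trials, n_sims = n_sims,
      ppi_ci = ppi_ci, pdi_ci = pdi_ci, pdi_nets = pdi_nets,
      n_contexts = n_contexts, correction = match.arg(correction),
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or take inputs; (2) Es and pmax profiles and
#' specificity classification; (3) class-composition summaries and
#' fold-difference / Monte-Carlo tests for ubiquitous-within,
#' specific-within, and specific-versus-ubiquitous edges; (4) regulatory
#' matched-specificity test against a degree-preserving null (skipped with
#' a notice when the regulatory network is empty); (5) pmax-filter sweep
#' over the focal conditions; (6) enrichment of the pmax gene lists per
#' focal condition, heat-map scaling, and context clustering (when at least
#' two contexts). If `out_dir` is given, every stage's table is written as
#' TSV/JSON along with a provenance record of all parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A named list of stage results (the report bundle).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  sim$seed <- child_seed(config$seed, 1)
  mode <- config$regime

  # --- inputs ---------------------------------------------------------
  if (is.null(config$expression) || is.null(config$ppi) ||
      is.null(config$pdi) || is.null(config$annotations)) {
    base <- simulate_expression_matrix(sim, mode)
    truth <- base$truth
  } else {
    base <- NULL
    truth <- NULL
  }
  expression <- config$expression %||% base$expression
  ppi <- config$ppi %||% simulate_ppi_network(truth, sim)$network
  pdi <- config$pdi %||% simulate_pdi_network(truth, sim)$network
  annotations <- config$annotations %||%
    simulate_annotations(truth, sim)$annotations

  # --- scales and classification -------------------------------------
  es <- compute_specificity(expression)
  pm <- compute_pmax(expression)
  classification <- classify_genes(es, classification_thresholds(mode))

  by_class <- split(classification$gene, classification$class)
  ubiq <- by_class$ubiquitous %||% character(0)
  spec <- by_class$specific %||% character(0)

  composition <- bind_rows(lapply(
    c("ubiquitous", "NUNS", "specific"),
    function(cl) {
      g <- by_class[[cl]] %||% character(0)
      if (length(intersect(g, network_nodes(ppi))) == 0) return(NULL)
      composition_by_class(ppi, g, classification, label = cl)
    }
  ))

  # --- PPI group statistics ------------------------------------------
  folds <- list(
    ubiquitous_within = fold_difference(
      ppi, ubiq, "within",
      n_trials = config$n_trials, seed = child_seed(config$seed, 11)
    ),
    specific_within = fold_difference(
      ppi, spec, "within",
      n_trials = config$n_trials, seed = child_seed(config$seed, 12)
    ),
    specific_vs_ubiquitous = fold_difference(
      ppi, spec, "between", fixed_set = ubiq,
      n_trials = config$n_trials, seed = child_seed(config$seed, 13)
    )
  )
  pvals <- list(
    ubiquitous_within = mc_pvalue(
      ppi, ubiq, "within",
      n_sims = config$n_sims, ci_level = config$ppi_ci, tail = "enriched",
      seed = child_seed(config$seed, 21)
    ),
    specific_within = mc_pvalue(
      ppi, spec, "within",
      n_sims = config$n_sims, ci_level = config$ppi_ci, tail = "depleted",
      seed = child_seed(config$seed, 22)
    ),
    specific_vs_ubiquitous = mc_pvalue(
      ppi, spec, "between", fixed_set = ubiq,
      n_sims = config$n_sims, ci_level = config$ppi_ci, tail = "enriched",
      seed = child_seed(config$seed, 23)
    )
  )
  fold_table <- bind_rows(lapply(folds, glance), .id = "test") |>
    left_join(
      bind_rows(lapply(pvals, tidy), .id = "test") |>
        select("test", "n_as_extreme", "p_value"),
      by = "test"
    )

  # --- regulatory network --------------------------------------------
  pdi_result <- if (nrow(pdi) == 0) {
    inform("regulatory network empty: PDI stages skipped")
    NULL
  } else {
    pdi_degree_null(
      pdi, classification,
      n_nets = config$pdi_nets, mode = "tf_degree",
      ci_level = config$pdi_ci, seed = child_seed(config$seed, 31),
      keep_null_counts = FALSE
    )
  }

  # --- context filters ------------------------------------------------
  spec_counts <- classification |>
    filter(.data$class == "specific", !is.na(.data$condition)) |>
    count(.data$condition, sort = TRUE)
  contexts <- head(spec_counts$condition, config$n_contexts)

  filter_reports <- bind_rows(lapply(contexts, function(ctx) {
    bind_rows(lapply(config$pmax_thresholds, function(th) {
      pmax_filter_network(ppi, pm, ctx, th)$report
    }))
  }))

  # --- enrichment and clustering -------------------------------------
  gene_lists <- lapply(contexts, function(ctx) {
    pmax_filter_genes(expression$gene, pm, ctx, 75)
  })
  names(gene_lists) <- contexts
  enrichment <- lapply(gene_lists, function(g) {
    term_enrichment(g, annotations, tail = "enriched",
                    correction = config$correction)
  })
  heat <- if (length(enrichment) >= 1) scale_log_pvalues(enrichment) else NULL
  clustering <- if (!is.null(heat) && ncol(heat) >= 2) {
    cluster_contexts(heat)
  } else {
    NULL
  }

  bundle <- list(
    expression = expression,
    classification = classification,
    composition = composition,
    folds = folds,
    fold_table = fold_table,
    pvalues = pvals,
    pdi_test = pdi_result,
    filter_reports = filter_reports,
    gene_lists = gene_lists,
    enrichment = enrichment,
    heatmap = heat,
    clustering = clustering,
    contexts = contexts,
    config = config
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_expression_table(bundle$expression, p("expression.tsv"))
  readr::write_tsv(bundle$classification, p("classification.tsv"), progress = FALSE)
  if (nrow(bundle$composition %||% tibble())) {
    readr::write_tsv(bundle$composition, p("composition.tsv"), progress = FALSE)
  }
  readr::write_tsv(bundle$fold_table, p("fold_differences.tsv"), progress = FALSE)
  readr::write_tsv(bundle$filter_reports, p("filter_reports.tsv"), progress = FALSE)
  for (ctx in names(bundle$enrichment)) {
    readr::write_tsv(
      bundle$enrichment[[ctx]], p(sprintf("enrichment_%s.tsv", ctx)),
      progress = FALSE
    )
  }
  if (!is.null(bundle$heatmap)) {
    readr::write_tsv(
      as_tibble(unclass(bundle$heatmap), rownames = "term"),
      p("heatmap_matrix.tsv"), progress = FALSE
    )
  }
  if (!is.null(bundle$clustering)) {
    writeLines(bundle$clustering$order, p("context_order.txt"))
  }
  if (!is.null(bundle$pdi_test)) {
    jsonlite::write_json(
      tidy(bundle$pdi_test), p("pdi_test.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  cfg <- bundle$config
  provenance <- list(
    regime = cfg$regime, seed = cfg$seed,
    n_trials = cfg$n_trials, n_sims = cfg$n_sims,
    ppi_ci = cfg$ppi_ci, pdi_ci = cfg$pdi_ci, pdi_nets = cfg$pdi_nets,
    pmax_thresholds = cfg$pmax_thresholds,
    correction = cfg$correction,
    contexts = bundle$contexts,
    sim = unclass(cfg$sim)
  )
  jsonlite::write_json(provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
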