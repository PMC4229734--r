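# Context (tissue/stage) networks and pmax-based filters.

profile_values <- function(profile, condition, value_col) {
  if (!condition %in% profile$condition) {
    abort(sprintf("condition %s not in profile", condition))
  }
  sub <- profile[profile$condition == condition, , drop = FALSE]
  setNames(sub[[value_col]], sub$gene)
}

#' Restrict a network to genes expressed in a condition
#'
#' Tissue-relevant networks keep genes with expression specificity above
#' zero in the tissue; stage-relevant networks keep genes with Es above
#' 0.005 in the stage. Genes without expression data are retained or dropped
#' per `missing_policy`.
#'
#' @param net A `ppi_network`.
#' @param profile An `es_profile` from [compute_specificity()].
#' @param condition Condition label.
#' @param regime `"tissue"` (Es > 0) or `"stage"` (Es > 0.005).
#' @param missing_policy Keep (`"retain"`) or remove (`"drop"`) genes absent
#'   from the expression profile.
#' @return Induced-subgraph `ppi_network`.
#' @export
context_network <- function(net, profile, condition,
                            regime = c("tissue", "stage"),
                            missing_policy = c("retain", "drop")) {
  regime <- match.arg(regime)
  missing_policy <- match.arg(missing_policy)
  floor_ <- if (regime == "tissue") 0 else 0.005
  es <- profile_values(profile, condition, "es")
  passes <- function(g) {
    v <- es[g]
    ifelse(is.na(v), missing_policy == "retain", v > floor_)
  }
  keep <- passes(net$from) & passes(net$to)
  out <- net[keep, , drop = FALSE]
  structure(out, directed = is_directed(net), class = class(net))
}

#' Genes passing a pmax threshold in a condition
#'
#' Strict threshold: a gene passes when its pmax in the condition exceeds
#' `threshold`. Genes without expression data have no pmax value and are
#' excluded from gene lists (network filtering treats them separately, see
#' [pmax_filter_network()]).
#'
#' @param genes Candidate gene IDs.
#' @param pmax_profile A `pmax_profile` from [compute_pmax()].
#' @param condition Condition label.
#' @param threshold pmax percent in (0, 100].
#' @return Character vector of passing genes.
#' @export
pmax_filter_genes <- function(genes, pmax_profile, condition, threshold) {
  stopifnot(threshold > 0, threshold <= 100)
  pm <- profile_values(pmax_profile, condition, "pmax")
  v <- pm[genes]
  genes[!is.na(v) & v > threshold]
}

#' pmax-filtered subnetwork
#'
#' A gene passes the filter when its pmax in the condition strictly exceeds
#' the threshold, or when it has no expression data and
#' `missing_policy = "retain"` (the default, so genes are not discarded just
#' because their expression is unknown). Only edges whose *both* endpoints
#' pass are kept; nodes left without edges drop out of the subnetwork.
#'
#' @inheritParams pmax_filter_genes
#' @param net A `ppi_network`.
#' @param missing_policy `"retain"` or `"drop"` for genes with no pmax value
#'   (not in the profile, or degenerate).
#' @return List with `network` (filtered `ppi_network`) and `report`
#'   (one-row tibble: threshold, condition, `genes_passing` (with data),
#'   `genes_retained_missing`, `genes_in_subnetwork`, `edges_in_subnetwork`,
#'   `dropped_isolated`).
#' @export
pmax_filter_network <- function(net, pmax_profile, condition, threshold,
                                missing_policy = c("retain", "drop")) {
  stopifnot(threshold > 0, threshold <= 100)
  missing_policy <- match.arg(missing_policy)
  pm <- profile_values(pmax_profile, condition, "pmax")
  nodes <- network_nodes(net)
  v <- pm[nodes]
  has_data <- !is.na(v)
  pass_data <- has_data & v > threshold
  pass_missing <- !has_data & missing_policy == "retain"
  pass <- setNames(pass_data | pass_missing, nodes)

  keep <- pass[net$from] & pass[net$to]
  sub <- net[keep, , drop = FALSE]
  sub_nodes <- unique(c(sub$from, sub$to))
  n_passing <- sum(pass_data)
  report <- tibble(
    threshold = threshold,
    condition = condition,
    missing_policy = missing_policy,
    genes_passing = n_passing,
    genes_retained_missing = sum(pass_missing),
    genes_in_subnetwork = length(sub_nodes),
    edges_in_subnetwork = nrow(sub),
    dropped_isolated = sum(pass) - length(sub_nodes)
  )
  list(
    network = structure(sub, directed = is_directed(net), class = class(net)),
    report = report
  )
}

#' Genes expressed above the condition-wide average
#'
#' Keeps genes whose abundance in the condition strictly exceeds the mean
#' abundance over all genes with data in that condition.
#'
#' @param genes Candidate gene IDs.
#' @param expr Wide expression tibble.
#' @param condition Condition column name.
#' @return Character vector of passing genes.
#' @export
average_expression_filter <- function(genes, expr, condition) {
  expr <- validate_expression(expr)
  if (!condition %in% names(expr)) {
    abort(sprintf("condition %s not in expression table", condition))
  }
  v <- setNames(expr[[condition]], expr$gene)
  avg <- mean(v, na.rm = TRUE)
  x <- v[genes]
  genes[!is.na(x) & x > avg]
}
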