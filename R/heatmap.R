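# Enrichment-profile heat-map scaling and hierarchical clustering of
# contexts.

#' Scale corrected enrichment p-values for a heat map
#'
#' Assembles a term-by-context matrix of `-log10(p_corrected)`, filling
#' term/context pairs absent from a context's result with 0, then min-max
#' scales to `[0, 1]` (globally by default, or per term row). A constant
#' matrix carries no contrast and maps to 0.5 everywhere, with a warning.
#'
#' @param results Named list mapping context labels to enrichment tibbles
#'   from [term_enrichment()].
#' @param scaling `"global"` or `"row"` min-max scaling.
#' @return A `heatmap_matrix`: numeric matrix (terms x contexts) in
#'   `[0, 1]`.
#' @export
scale_log_pvalues <- function(results, scaling = c("global", "row")) {
  scaling <- match.arg(scaling)
  stopifnot(length(results) >= 1, !is.null(names(results)))
  terms <- sort(unique(unlist(lapply(results, function(r) r$term))))
  contexts <- names(results)
  m <- matrix(0, nrow = length(terms), ncol = length(contexts),
              dimnames = list(terms, contexts))
  for (ctx in contexts) {
    r <- results[[ctx]]
    if (nrow(r)) m[r$term, ctx] <- -log10(r$p_corrected)
  }
  rescale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warn("constant values: scaled matrix set to 0.5")
      return(x * 0 + 0.5)
    }
    (x - rng[1]) / diff(rng)
  }
  scaled <- if (scaling == "global") {
    rescale01(m)
  } else {
    t(apply(m, 1, rescale01))
  }
  structure(scaled, class = c("heatmap_matrix", "matrix", "array"))
}

#' Hierarchically cluster contexts by their enrichment profiles
#'
#' Agglomerative clustering of the context columns of a scaled enrichment
#' matrix. Deterministic given its inputs.
#'
#' @param matrix A `heatmap_matrix` from [scale_log_pvalues()] (or any
#'   numeric matrix, terms x contexts).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @return List with `order` (context labels in dendrogram order) and
#'   `hclust` (the fitted tree).
#' @export
cluster_contexts <- function(matrix, linkage = "average",
                             distance = "euclidean") {
  if (ncol(matrix) < 2) abort("need at least 2 contexts to cluster")
  d <- dist(t(unclass(matrix)), method = distance)
  hc <- hclust(d, method = linkage)
  list(order = colnames(matrix)[hc$order], hclust = hc)
}
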