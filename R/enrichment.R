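# Annotation-term enrichment / depletion by hypergeometric tails.

#' Term enrichment and depletion for a gene list
#'
#' One-sided hypergeometric tail probability for every annotation term:
#' with N background genes, K of them annotated with the term, a query of n
#' genes containing k annotated ones, the enriched tail is P(X >= k) and the
#' depleted tail P(X <= k). Multiple-testing correction is applied across
#' the tested terms (Bonferroni or Benjamini-Hochberg), and results are
#' sorted by corrected p-value. Query genes outside the background are
#' dropped with a message; terms annotating no background genes are
#' skipped.
#'
#' @param query Character vector of gene IDs.
#' @param annotations An [annotation_set()].
#' @param tail `"enriched"` or `"depleted"`.
#' @param correction `"bonferroni"` or `"bh"`.
#' @return Tibble (`term`, `k`, `n`, `K`, `N`, `fold`, `p_raw`,
#'   `p_corrected`, `tail`) sorted by `p_corrected`.
#' @examples
#' ann <- annotation_set(list(t1 = c("a", "b")), letters[1:10])
#' term_enrichment(c("a", "b", "c"), ann)
#' @export
term_enrichment <- function(query, annotations,
                            tail = c("enriched", "depleted"),
                            correction = c("bonferroni", "bh")) {
  tail <- match.arg(tail)
  correction <- match.arg(correction)
  stopifnot(inherits(annotations, "annotation_set"))
  bg <- annotations$background
  if (length(bg) == 0) abort("empty background")
  query <- unique(query)
  outside <- setdiff(query, bg)
  if (length(outside)) {
    inform(sprintf("%d query gene(s) not in background, dropped", length(outside)))
  }
  query <- intersect(query, bg)
  n <- length(query)
  N <- length(bg)
  terms <- annotations$terms
  Ks <- vapply(terms, length, integer(1))
  terms <- terms[Ks > 0]
  if (length(terms) == 0) {
    return(tibble(
      term = character(), k = integer(), n = integer(), K = integer(),
      N = integer(), fold = double(), p_raw = double(),
      p_corrected = double(), tail = character()
    ))
  }
  ks <- vapply(terms, function(g) length(intersect(g, query)), integer(1))
  Ks <- vapply(terms, length, integer(1))
  p_raw <- if (tail == "enriched") {
    phyper(ks - 1, Ks, N - Ks, n, lower.tail = FALSE)
  } else {
    phyper(ks, Ks, N - Ks, n, lower.tail = TRUE)
  }
  p_corr <- p.adjust(p_raw, method = if (correction == "bh") "BH" else "bonferroni")
  fold <- if (n > 0) (ks / n) / (Ks / N) else NA_real_
  tibble(
    term = names(terms), k = unname(ks), n = n, K = unname(Ks), N = N,
    fold = unname(fold), p_raw = unname(p_raw),
    p_corrected = unname(p_corr), tail = tail
  ) |>
    arrange(.data$p_corrected, .data$p_raw, .data$term)
}
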