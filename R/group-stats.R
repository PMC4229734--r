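# Edge-count statistics for gene classes in interaction networks.

#' Count edges within a gene set
#'
#' @param net A `ppi_network`.
#' @param genes Character vector of gene IDs.
#' @return Number of edges with both endpoints in `genes`.
#' @export
count_edges_within <- function(net, genes) {
  sum(net$from %in% genes & net$to %in% genes)
}

#' Count edges between two disjoint gene sets
#'
#' Genes in both sets are excluded, so between-counts never overlap
#' within-counts: for a partition `{A, B}` of the nodes,
#' `within(A) + within(B) + between(A, B)` equals the edge total.
#'
#' @param net A `ppi_network`.
#' @param set_a,set_b Character vectors of gene IDs.
#' @return Number of edges with one endpoint in `A \ B`, the other in
#'   `B \ A`.
#' @export
count_edges_between <- function(net, set_a, set_b) {
  a <- setdiff(set_a, set_b)
  b <- setdiff(set_b, set_a)
  sum((net$from %in% a & net$to %in% b) | (net$from %in% b & net$to %in% a))
}

#' Count indirect interactions within a gene set
#'
#' An indirect interaction is an unordered pair of distinct set members that
#' are *not* directly connected but share at least one common neighbor
#' outside the set (optionally restricted to `intermediates`).
#'
#' @param net A `ppi_network`.
#' @param genes Character vector of gene IDs.
#' @param intermediates Candidate third proteins; default all network nodes.
#' @return Number of qualifying pairs.
#' @export
count_indirect_pairs <- function(net, genes, intermediates = NULL) {
  intermediates <- intermediates %||% network_nodes(net)
  mids <- setdiff(intersect(intermediates, network_nodes(net)), genes)
  if (length(mids) == 0) return(0L)
  # neighbors-in-set of each candidate intermediate
  e_from_mid <- net$from %in% mids & net$to %in% genes
  e_to_mid <- net$to %in% mids & net$from %in% genes
  nb <- c(
    split(net$to[e_from_mid], net$from[e_from_mid]),
    split(net$from[e_to_mid], net$to[e_to_mid])
  )
  nb <- tapply(unlist(nb), rep(names(nb), lengths(nb)), unique, simplify = FALSE)
  pairs <- unique(unlist(lapply(nb, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2) return(character(0))
    cmb <- combn(g, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })))
  if (length(pairs) == 0) return(0L)
  direct <- paste(pmin(net$from, net$to), pmax(net$from, net$to), sep = "\r")
  sum(!(pairs %in% direct))
}

#' Unique interactions per protein for a gene set
#'
#' Number of network edges incident to at least one set member (each edge
#' counted once, even when both endpoints are members) divided by the number
#' of set members present in the network.
#'
#' @inheritParams count_edges_within
#' @return Interactions-per-protein ratio.
#' @export
interactions_per_protein <- function(net, genes) {
  members <- intersect(genes, network_nodes(net))
  if (length(members) == 0) {
    abort("none of the genes are in the network")
  }
  n_edges <- sum(net$from %in% members | net$to %in% members)
  n_edges / length(members)
}

#' Interaction-partner composition of a gene set
#'
#' For every network edge incident to the gene set, tallies the specificity
#' class of the interaction partner and reports the percentages of
#' interactions with ubiquitous, NUNS, and specific partners (unclassified
#' partners are excluded from the percentages and reported separately).
#' With `by_source = TRUE` the summary is computed per interaction data
#' source (edges carrying several source labels count once per label).
#'
#' @param net A `ppi_network`.
#' @param genes Character vector defining the protein group.
#' @param classification Tibble (`gene`, `class`) from [classify_genes()].
#' @param label Group label for the output row.
#' @param by_source Split the tally by edge source label.
#' @param percent_decimals Decimal places for the reported percentages.
#' @return Tibble with columns `group`, `source` (if `by_source`),
#'   `n_proteins`, `interactions_per_protein`, `total_interactions`,
#'   `pct_ubiquitous`, `pct_nuns`, `pct_specific`,
#'   `n_unclassified_partners`.
#' @export
composition_by_class <- function(net, genes, classification,
                                 label = "group", by_source = FALSE,
                                 percent_decimals = 1) {
  cls <- setNames(classification$class, classification$gene)
  one_summary <- function(sub, src) {
    members <- intersect(genes, unique(c(sub$from, sub$to)))
    incident <- sub$from %in% members | sub$to %in% members
    sub <- sub[incident, , drop = FALSE]
    partner <- ifelse(sub$from %in% members, sub$to, sub$from)
    pc <- cls[partner]
    pc[is.na(pc)] <- "unclassified"
    known <- pc[pc %in% c("ubiquitous", "NUNS", "specific")]
    denom <- length(known)
    pct <- function(class_name) {
      if (denom == 0) return(NA_real_)
      percent_of(sum(known == class_name), denom, percent_decimals)
    }
    tibble(
      group = label,
      source = src,
      n_proteins = length(members),
      interactions_per_protein = if (length(members)) {
        nrow(sub) / length(members)
      } else {
        NA_real_
      },
      total_interactions = nrow(sub),
      pct_ubiquitous = pct("ubiquitous"),
      pct_nuns = pct("NUNS"),
      pct_specific = pct("specific"),
      n_unclassified_partners = sum(pc == "unclassified")
    )
  }
  if (!by_source) {
    out <- one_summary(net, NA_character_)
    return(select(out, -"source"))
  }
  labels <- sort(unique(unlist(net$sources)))
  bind_rows(lapply(labels, function(s) {
    keep <- vapply(net$sources, function(x) s %in% x, logical(1))
    one_summary(net[keep, , drop = FALSE], s)
  }))
}
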