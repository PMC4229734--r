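# Interaction-network container: a tibble of edges (`from`, `to`, `sources`
# list-column) with a `directed` attribute. Undirected edges are stored
# canonically (from <= to lexicographically) so {a,b} and {b,a} are one edge.

#' Build an interaction or regulatory network from an edge data frame
#'
#' Drops self-edges, canonicalizes undirected pairs, and collapses duplicate
#' rows, unioning their source labels. The result is a tibble with columns
#' `from`, `to`, and `sources` (a list-column of character vectors), carrying
#' a `directed` attribute.
#'
#' @param edges Data frame with at least two character columns (interactor A,
#'   interactor B); an optional `source` (or `sources`) column labels the
#'   data set each row came from.
#' @param directed `FALSE` for protein-protein interactions, `TRUE` for
#'   TF -> target regulatory edges.
#' @return A `ppi_network` tibble.
#' @examples
#' as_network(data.frame(from = c("a", "b", "a"), to = c("b", "a", "a")))
#' @export
as_network <- function(edges, directed = FALSE) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  src <- if ("sources" %in% names(edges)) {
    edges$sources
  } else if ("source" %in% names(edges)) {
    lapply(as.character(edges$source), function(s) s[!is.na(s) & nzchar(s)])
  } else if (ncol(edges) >= 3 && !is.list(edges[[3]])) {
    lapply(as.character(edges[[3]]), function(s) s[!is.na(s) & nzchar(s)])
  } else {
    rep(list(character(0)), length(from))
  }

  keep <- !is.na(from) & !is.na(to) & from != to
  n_self <- sum(from == to, na.rm = TRUE)
  if (n_self > 0) {
    inform(sprintf("dropped %d self-edge row(s)", n_self))
  }
  from <- from[keep]
  to <- to[keep]
  src <- src[keep]

  if (!directed) {
    swap <- from > to
    tmp <- from[swap]
    from[swap] <- to[swap]
    to[swap] <- tmp
  }

  key <- paste(from, to, sep = "\r")
  first <- !duplicated(key)
  sources <- lapply(
    split(src, factor(key, levels = key[first])),
    function(x) sort(unique(unlist(x)))
  )
  out <- tibble(from = from[first], to = to[first], sources = unname(sources))
  structure(out, directed = directed, class = c("ppi_network", class(out)))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<%s network: %d edges, %d nodes>\n",
    if (is_directed(x)) "directed" else "undirected",
    nrow(x), length(network_nodes(x))
  ))
  NextMethod()
}

#' @rdname as_network
#' @param net A `ppi_network`.
#' @export
is_directed <- function(net) {
  isTRUE(attr(net, "directed"))
}

#' Nodes of a network
#'
#' The node universe is the set of genes incident to at least one edge
#' (isolated nodes are not representable in an edge list).
#'
#' @param net A `ppi_network`.
#' @return Sorted character vector of gene IDs.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$from, net$to)))
}

#' Read a delimited edge list
#'
#' Parses two-column-plus-optional-source tables (`geneA<TAB>geneB[<TAB>source]`
#' by default). Self-edges are dropped with a message, duplicates collapsed
#' with their sources unioned, and undirected pairs canonicalized.
#'
#' @param path File to read.
#' @param directed Whether edges are ordered (TF -> target) pairs.
#' @param delim Field delimiter (default tab).
#' @param col_names Whether the file has a header row.
#' @return A `ppi_network` tibble.
#' @export
read_edge_list <- function(path, directed = FALSE, delim = "\t",
                           col_names = TRUE) {
  df <- readr::read_delim(
    path,
    delim = delim, col_names = col_names, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(df) < 2) {
    stop_parse("edge list %s must have at least 2 columns", path)
  }
  if (anyNA(df[[1]]) || anyNA(df[[2]])) {
    stop_parse("edge list %s has missing gene IDs", path)
  }
  as_network(df, directed = directed)
}

#' Merge networks by edge union
#'
#' @param ... Networks (or a single list of networks) of identical
#'   directedness.
#' @return A `ppi_network` with the union of edges; sources are unioned on
#'   shared edges.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1 && !is.data.frame(nets[[1]])) nets <- nets[[1]]
  stopifnot(length(nets) >= 1)
  dirs <- vapply(nets, is_directed, logical(1))
  if (length(unique(dirs)) != 1) {
    abort("cannot merge directed and undirected networks")
  }
  all_edges <- bind_rows(lapply(nets, function(n) {
    tibble(from = n$from, to = n$to, sources = n$sources)
  }))
  as_network(all_edges, directed = dirs[1])
}

#' Filter network edges by data source
#'
#' An edge survives when at least one of its source labels is admissible:
#' in `include` (include mode) or outside `exclude` (exclude mode). Edges
#' with several sources therefore survive exclusion of one of them, matching
#' the convention of re-analysing a network "with interologs removed" while
#' keeping edges that also have experimental support.
#'
#' @param net A `ppi_network` with source labels.
#' @param include Keep edges with at least one of these sources.
#' @param exclude Keep edges with at least one source not among these.
#' @return Filtered `ppi_network`.
#' @export
filter_by_source <- function(net, include = NULL, exclude = NULL) {
  if (is.null(include) == is.null(exclude)) {
    abort("supply exactly one of `include` or `exclude`")
  }
  all_src <- unique(unlist(net$sources))
  asked <- c(include, exclude)
  unknown <- setdiff(asked, all_src)
  if (length(unknown)) {
    warn(sprintf("source label(s) not present: %s", toString(unknown)))
  }
  keep <- if (!is.null(include)) {
    vapply(net$sources, function(s) any(s %in% include), logical(1))
  } else {
    vapply(net$sources, function(s) length(setdiff(s, exclude)) > 0, logical(1))
  }
  out <- net[keep, , drop = FALSE]
  structure(out, directed = is_directed(net), class = class(net))
}

#' Extract the neighborhood of seed genes
#'
#' Induced subgraph on the seeds plus every node within `depth` hops of any
#' seed. Seeds absent from the network are reported via the
#' `missing_seeds` attribute.
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of seed gene IDs (non-empty).
#' @param depth Hop limit (>= 1).
#' @return A `ppi_network` with attribute `missing_seeds`.
#' @export
neighborhood_extract <- function(net, seeds, depth = 1) {
  if (length(seeds) == 0) abort("empty seed list")
  stopifnot(depth >= 1)
  nodes <- network_nodes(net)
  missing <- setdiff(seeds, nodes)
  present <- intersect(seeds, nodes)
  if (length(missing)) {
    inform(sprintf("%d seed(s) not in network: %s",
                   length(missing), toString(head(missing, 5))))
  }
  if (length(present) == 0) {
    out <- net[0, , drop = FALSE]
  } else {
    g <- igraph::graph_from_data_frame(
      net[, c("from", "to")],
      directed = is_directed(net)
    )
    hood <- igraph::ego(g, order = depth, nodes = present, mode = "all")
    keep_nodes <- unique(names(unlist(hood)))
    out <- net[net$from %in% keep_nodes & net$to %in% keep_nodes, , drop = FALSE]
  }
  structure(out,
    directed = is_directed(net), class = class(net),
    missing_seeds = missing
  )
}

#' Write a network to TSV or SIF
#'
#' TSV round-trips losslessly through [read_edge_list()] (one row per edge
#' and source; sourceless edges get an empty source field). SIF uses a fixed
#' relation token (`pp` undirected, `pd` directed).
#'
#' @param net A `ppi_network`.
#' @param path Output file.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- purrr::pmap(
      list(net$from, net$to, net$sources),
      function(f, t, s) {
        if (length(s) == 0) s <- ""
        tibble(geneA = f, geneB = t, source = s)
      }
    )
    df <- if (length(rows)) bind_rows(rows) else {
      tibble(geneA = character(), geneB = character(), source = character())
    }
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    rel <- if (is_directed(net)) "pd" else "pp"
    lines <- sprintf("%s %s %s", net$from, rel, net$to)
    writeLines(lines, path)
  }
  invisible(path)
}
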