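# Degree-preserving null models for the TF -> target regulatory network.

#' Matched-specificity edge count of a regulatory network
#'
#' Number of TF -> target edges where both the TF and the target are
#' classified as specific to the *same* condition.
#'
#' @param regnet Directed `ppi_network` (TF -> target).
#' @param classification Tibble (`gene`, `class`, `condition`) from
#'   [classify_genes()].
#' @return Integer count.
#' @export
matched_specific_count <- function(regnet, classification) {
  spec <- setNames(classification$class == "specific", classification$gene)
  home <- setNames(classification$condition, classification$gene)
  sf <- spec[regnet$from]
  st <- spec[regnet$to]
  hf <- home[regnet$from]
  ht <- home[regnet$to]
  sum(!is.na(sf) & !is.na(st) & sf & st &
        !is.na(hf) & !is.na(ht) & hf == ht)
}

#' One degree-preserving randomization of a regulatory network
#'
#' `tf_degree` mode keeps each TF's out-degree and assigns its targets by
#' uniform sampling without replacement from the full target pool (the
#' literal "random targets, node degree constant" null).
#' `both_degrees` mode additionally preserves every target's in-degree via
#' bipartite double-edge swaps (degree-sequence-preserving rewiring).
#'
#' @inheritParams matched_specific_count
#' @param mode `"tf_degree"` or `"both_degrees"`.
#' @param seed Integer seed.
#' @return Tibble (`from`, `to`) of the randomized edges.
#' @export
pdi_null_network <- function(regnet, mode = c("tf_degree", "both_degrees"),
                             seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "tf_degree") {
      pool <- unique(regnet$to)
      deg <- table(regnet$from)
      tfs <- names(deg)
      to <- unlist(lapply(as.integer(deg), function(d) {
        pool[sample.int(length(pool), d)]
      }), use.names = FALSE)
      tibble(from = rep(tfs, as.integer(deg)), to = to)
    } else {
      g <- igraph::graph_from_data_frame(
        regnet[, c("from", "to")],
        directed = TRUE
      )
      g2 <- igraph::rewire(
        g,
        igraph::keeping_degseq(niter = max(10L * nrow(regnet), 100L))
      )
      el <- igraph::as_edgelist(g2)
      tibble(from = el[, 1], to = el[, 2])
    }
  })
}

#' Monte-Carlo test of matched-specificity enrichment in a regulatory network
#'
#' Compares the observed number of same-condition-specific TF -> target
#' edges with its distribution over degree-preserving random networks
#' (see [pdi_null_network()]). The p-value is the upper Clopper-Pearson
#' binomial confidence bound for the fraction of null networks with a
#' matched count at least as extreme as the observed one.
#'
#' @inheritParams pdi_null_network
#' @param n_nets Number of random networks (default 100,000).
#' @param ci_level Confidence level of the binomial interval (default 0.95).
#' @param tail `"enriched"` (null counts >= observed) or `"depleted"`.
#' @param keep_null_counts Attach the vector of null statistics to the
#'   result (for diagnostics; default `TRUE`).
#' @return An `mc_pvalue` object with extra fields `null_mean` and (if kept)
#'   `null_counts`.
#' @export
pdi_degree_null <- function(regnet, classification, n_nets = 1e5,
                            mode = c("tf_degree", "both_degrees"),
                            ci_level = 0.95,
                            tail = c("enriched", "depleted"),
                            seed = NULL, keep_null_counts = TRUE) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  if (n_nets < 1) abort("n_nets must be at least 1")
  if (nrow(regnet) == 0) abort("empty regulatory network")
  observed <- matched_specific_count(regnet, classification)

  spec <- setNames(classification$class == "specific", classification$gene)
  home <- setNames(classification$condition, classification$gene)

  with_seed(seed, {
    nulls <- integer(n_nets)
    if (mode == "tf_degree") {
      # only specific TFs can contribute matched edges; precompute, per
      # specific TF, which pool targets are specific to its home condition
      pool <- unique(regnet$to)
      deg <- table(regnet$from)
      tfs <- names(deg)
      is_spec_tf <- !is.na(spec[tfs]) & spec[tfs] & !is.na(home[tfs])
      flags <- lapply(tfs[is_spec_tf], function(tf) {
        !is.na(spec[pool]) & spec[pool] &
          !is.na(home[pool]) & home[pool] == home[[tf]]
      })
      degs <- as.integer(deg[tfs[is_spec_tf]])
      np <- length(pool)
      for (i in seq_len(n_nets)) {
        s <- 0L
        for (j in seq_along(flags)) {
          s <- s + sum(flags[[j]][sample.int(np, degs[j])])
        }
        nulls[i] <- s
      }
    } else {
      g <- igraph::graph_from_data_frame(
        regnet[, c("from", "to")],
        directed = TRUE
      )
      niter <- max(10L * nrow(regnet), 100L)
      for (i in seq_len(n_nets)) {
        g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
        el <- igraph::as_edgelist(g2)
        sf <- spec[el[, 1]]
        st <- spec[el[, 2]]
        hf <- home[el[, 1]]
        ht <- home[el[, 2]]
        nulls[i] <- sum(!is.na(sf) & !is.na(st) & sf & st &
                          !is.na(hf) & !is.na(ht) & hf == ht)
      }
    }
    n_extreme <- if (tail == "enriched") {
      sum(nulls >= observed)
    } else {
      sum(nulls <= observed)
    }
    out <- list(
      observed = observed,
      n_sims = n_nets,
      n_as_extreme = n_extreme,
      ci_level = ci_level,
      tail = tail,
      p_value = cp_upper(n_extreme, n_nets, ci_level),
      null_mean = mean(nulls),
      mode = mode,
      seed = seed
    )
    if (keep_null_counts) out$null_counts <- nulls
    structure(out, class = "mc_pvalue")
  })
}
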