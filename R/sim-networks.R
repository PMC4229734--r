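# Synthetic PPI / regulatory networks with planted class-pair structure.
#
# Degree heterogeneity comes from per-gene activity weights drawn from a
# Pareto distribution (tail exponent `degree_exponent`); an edge {i,j} is
# sampled with probability proportional to w_i * w_j * M[class_i, class_j].
#
# The configured fold_uu / fold_ss / fold_us are *target measured folds*:
# the fold-difference estimator compares a class's internal edge count to
# random sets drawn from the rest of the network, so its baseline mixes the
# propensities of the complement classes. ppi_propensity_matrix() solves the
# two-equation linear fixed point that makes the measured folds equal the
# configured ones (all NUNS-involving pairs are the unit baseline).

# Truncated Pareto activity weights. The cap keeps the largest pairwise
# edge probability below the Bernoulli ceiling, so planted class-pair
# propensities stay multiplicative (unsaturated) for hub-hub pairs.
pareto_weights <- function(n, exponent, cap = 8) {
  pmin(runif(n)^(-1 / exponent), cap)
}

# Convert target fold differences into class-pair propensity multipliers.
# p = proportions (ubiquitous, NUNS, specific). Returns 3x3 symmetric matrix
# indexed by class name.
ppi_propensity_matrix <- function(fold_uu, fold_ss, fold_us, p) {
  pu <- p[[1]]; pn <- p[[2]]; ps <- p[[3]]
  m <- matrix(1, 3, 3, dimnames = list(
    c("ubiquitous", "NUNS", "specific"),
    c("ubiquitous", "NUNS", "specific")
  ))
  # fold_uu = M_uu / baseline_u, baseline_u = mean propensity among pairs of
  # the complement (NUNS + specific); symmetrically for fold_ss.
  # M_uu = a1 + b1 * M_ss ; M_ss = a2 + b2 * M_uu  (linear, solve directly)
  a1 <- fold_uu * (pn^2 + 2 * pn * ps) / (pn + ps)^2
  b1 <- fold_uu * ps^2 / (pn + ps)^2
  a2 <- fold_ss * (2 * pu * pn + pn^2) / (pu + pn)^2
  b2 <- fold_ss * pu^2 / (pu + pn)^2
  m_uu <- (a1 + b1 * a2) / (1 - b1 * b2)
  m_ss <- a2 + b2 * m_uu
  if (!is.finite(m_uu) || !is.finite(m_ss) || m_uu < 0 || m_ss < 0) {
    stop_config("planted folds are infeasible for these class proportions")
  }
  m["ubiquitous", "ubiquitous"] <- m_uu
  m["specific", "specific"] <- m_ss
  # between-mode baseline is the NUNS-ubiquitous propensity (= 1)
  m["ubiquitous", "specific"] <- m["specific", "ubiquitous"] <- fold_us
  m
}

#' Simulate a protein-protein interaction network with planted class structure
#'
#' Samples an undirected network over the genes of a planted-truth table with
#' heavy-tailed degrees and class-pair edge propensities calibrated so that
#' [fold_difference()] recovers the configured `fold_uu`, `fold_ss`, and
#' `fold_us` (see [sim_config()]). No self-edges, no duplicates.
#'
#' @param truth Planted-truth tibble (`gene`, `class`, `condition`) from
#'   [simulate_expression_matrix()].
#' @param config A [sim_config()].
#' @return A list with `network` (a `ppi_network`; edges carry a synthetic
#'   source label `"sim"`) and `edge_classes` (tibble `from`, `to`,
#'   `pair_class` giving the unordered planted class pair of each edge).
#' @export
simulate_ppi_network <- function(truth, config) {
  validate_sim_config(config)
  stopifnot(all(c("gene", "class") %in% names(truth)))
  n <- nrow(truth)
  cls <- truth$class
  m <- ppi_propensity_matrix(
    config$fold_uu, config$fold_ss, config$fold_us,
    config$class_proportions
  )

  with_seed(child_seed(config$seed, 201), {
    w <- pareto_weights(n, config$degree_exponent)
    cls_i <- match(cls, rownames(m))

    # closed-form expected pair-weight total; calibrates the base rate so the
    # expected edge count is n * mean_degree / 2
    s_c <- tapply(w, cls_i, sum)
    q_c <- tapply(w^2, cls_i, sum)
    s_c <- s_c[as.character(1:3)]; s_c[is.na(s_c)] <- 0
    q_c <- q_c[as.character(1:3)]; q_c[is.na(q_c)] <- 0
    total <- 0
    for (a in 1:3) {
      for (b in a:3) {
        pair_sum <- if (a == b) (s_c[a]^2 - q_c[a]) / 2 else s_c[a] * s_c[b]
        total <- total + m[a, b] * pair_sum
      }
    }
    target_edges <- n * config$mean_degree / 2
    base <- target_edges / total

    from_idx <- integer(0)
    to_idx <- integer(0)
    block <- max(1L, floor(2e6 / n))
    i <- 1L
    while (i < n) {
      rows <- i:min(i + block - 1L, n - 1L)
      # upper-triangle probabilities for this row block
      pm <- outer(w[rows], w, "*") *
        matrix(m[cbind(rep(cls_i[rows], n), rep(cls_i, each = length(rows)))],
               nrow = length(rows)) * base
      pm <- pmin(pm, 0.95)
      keep_mask <- outer(rows, seq_len(n), "<")
      hits <- which(keep_mask & matrix(runif(length(pm)), nrow = length(rows)) < pm)
      if (length(hits)) {
        hr <- ((hits - 1L) %% length(rows)) + 1L
        hc <- ((hits - 1L) %/% length(rows)) + 1L
        from_idx <- c(from_idx, rows[hr])
        to_idx <- c(to_idx, hc)
      }
      i <- i + block
    }

    net <- as_network(
      tibble(
        from = truth$gene[from_idx],
        to = truth$gene[to_idx],
        source = "sim"
      ),
      directed = FALSE
    )
    pair_class <- vapply(seq_along(from_idx), function(k) {
      paste(sort(c(cls[from_idx[k]], cls[to_idx[k]])), collapse = "-")
    }, character(1))
    edge_classes <- tibble(
      from = pmin(truth$gene[from_idx], truth$gene[to_idx]),
      to = pmax(truth$gene[from_idx], truth$gene[to_idx]),
      pair_class = pair_class
    )
    list(network = net, edge_classes = distinct(edge_classes))
  })
}

#' Simulate a TF -> target regulatory network
#'
#' Chooses `n_tf` transcription factors stratified by planted class (so the
#' TF set mirrors the configured class proportions), draws heavy-tailed TF
#' out-degrees around `pdi_out_degree`, and samples targets uniformly except
#' that a specific TF oversamples targets specific to its own home condition
#' by `pdi_matched_fold`.
#'
#' @inheritParams simulate_ppi_network
#' @return A list with `network` (directed `ppi_network`), `tfs` (character
#'   vector), and `matched_pairs` (tibble of planted same-condition-specific
#'   TF -> target edges actually present in the network).
#' @export
simulate_pdi_network <- function(truth, config) {
  validate_sim_config(config)
  n <- nrow(truth)
  stopifnot(config$n_tf <= n)

  with_seed(child_seed(config$seed, 301), {
    counts <- class_counts(config$n_tf, config$class_proportions)
    tf_ids <- unlist(lapply(names(counts), function(cl) {
      pool <- truth$gene[truth$class == cl]
      sample(pool, min(counts[[cl]], length(pool)))
    }))
    # top up if a class pool was too small
    if (length(tf_ids) < config$n_tf) {
      extra <- sample(setdiff(truth$gene, tf_ids), config$n_tf - length(tf_ids))
      tf_ids <- c(tf_ids, extra)
    }

    v <- pareto_weights(length(tf_ids), config$degree_exponent)
    deg <- pmax(1L, round(config$pdi_out_degree * v / mean(v)))
    deg <- pmin(deg, n - 1L)

    home <- setNames(truth$condition, truth$gene)
    is_specific <- setNames(truth$class == "specific", truth$gene)

    edges <- purrr::map2(tf_ids, deg, function(tf, d) {
      pool <- truth$gene[truth$gene != tf]
      w <- rep(1, length(pool))
      if (isTRUE(is_specific[[tf]])) {
        matched <- is_specific[pool] & !is.na(home[pool]) &
          home[pool] == home[[tf]]
        w[matched] <- config$pdi_matched_fold
      }
      # independent inclusion with probability proportional to weight (capped
      # at 1 by water-filling), so the planted matched fold stays exactly
      # multiplicative in expectation; realized out-degree varies around d
      pi <- pmin(1, d * w / sum(w))
      for (i in 1:5) {
        free <- pi < 1
        short <- d - sum(pi[!free])
        if (short <= 0 || !any(free)) break
        pi[free] <- pmin(1, w[free] * short / sum(w[free]))
      }
      tibble(from = tf, to = pool[runif(length(pool)) < pi])
    })
    edges <- bind_rows(edges)
    net <- as_network(mutate(edges, source = "sim"), directed = TRUE)
    matched <- net$from %in% truth$gene[truth$class == "specific"] &
      !is.na(home[net$from]) & !is.na(home[net$to]) &
      home[net$from] == home[net$to] & is_specific[net$to]
    list(
      network = net,
      tfs = sort(unique(tf_ids)),
      matched_pairs = tibble(from = net$from[matched], to = net$to[matched])
    )
  })
}
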