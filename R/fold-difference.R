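# Fold differences against size-matched random gene sets, and Monte-Carlo
# p-values from binomial (Clopper-Pearson) confidence bounds.

# Upper bound of the two-sided exact (Clopper-Pearson) binomial confidence
# interval for x successes in n trials at confidence `ci_level`. The closed
# form for x = 0 is 1 - (alpha/2)^(1/n).
cp_upper <- function(x, n, ci_level) {
  stopifnot(x >= 0, x <= n, n >= 1, ci_level > 0, ci_level < 1)
  alpha <- 1 - ci_level
  if (x >= n) return(1)
  qbeta(1 - alpha / 2, x + 1, n - x)
}

# Shared Monte-Carlo engine: counts for `n_draws` random gene sets of size
# |test_set|, drawn uniformly without replacement from
# universe \ test_set (\ fixed_set in between mode).
random_set_counts <- function(net, test_set, mode, fixed_set, universe,
                              n_draws, intermediates = NULL) {
  pool <- setdiff(universe, test_set)
  if (mode == "between") pool <- setdiff(pool, fixed_set)
  k <- length(test_set)
  if (length(pool) < k) {
    abort(sprintf(
      "universe too small: %d candidate genes for sets of size %d",
      length(pool), k
    ))
  }
  nodes <- unique(c(net$from, net$to, pool, fixed_set))
  ef <- match(net$from, nodes)
  et <- match(net$to, nodes)
  pool_idx <- match(pool, nodes)
  mem <- logical(length(nodes))
  if (mode == "between") {
    fmem <- logical(length(nodes))
    fmem[match(intersect(fixed_set, nodes), nodes)] <- TRUE
  }
  counts <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    pick <- pool_idx[sample.int(length(pool_idx), k)]
    if (mode == "indirect") {
      counts[i] <- count_indirect_pairs(net, nodes[pick], intermediates)
    } else {
      mem[pick] <- TRUE
      counts[i] <- if (mode == "within") {
        sum(mem[ef] & mem[et])
      } else {
        sum((mem[ef] & fmem[et]) | (mem[et] & fmem[ef]))
      }
      mem[pick] <- FALSE
    }
  }
  counts
}

observed_count <- function(net, test_set, mode, fixed_set, intermediates) {
  switch(mode,
    within = count_edges_within(net, test_set),
    between = count_edges_between(net, test_set, fixed_set),
    indirect = count_indirect_pairs(net, test_set, intermediates)
  )
}

#' Fold difference in interactions versus random gene sets
#'
#' Compares the number of interactions among (or, in between mode, toward a
#' fixed set from) a test gene set with the counts obtained for random gene
#' sets of the same size drawn from the network universe minus the test set
#' (and minus the fixed set in between mode). The per-trial fold is the
#' observed count divided by the random count, with a floor of 1 on the
#' denominator to avoid division by zero (floored trials are reported).
#'
#' @param net A `ppi_network`.
#' @param test_set Character vector of gene IDs under test.
#' @param mode `"within"` (edges inside the set), `"between"` (edges between
#'   the set and `fixed_set`), or `"indirect"` (pairs of set members sharing
#'   an outside common neighbor, see [count_indirect_pairs()]).
#' @param fixed_set Second gene set held constant in between mode.
#' @param n_trials Number of random sets (default 5000).
#' @param universe Genes random sets are drawn from; default all network
#'   nodes.
#' @param intermediates Passed to [count_indirect_pairs()] in indirect mode.
#' @param seed Integer seed for reproducible draws.
#' @return A `fold_diff` object: observed count, per-trial random counts and
#'   folds, mean and SD fold, direction, and the number of floored trials.
#'   Use [tidy()]/[glance()] to get tibbles.
#' @export
fold_difference <- function(net, test_set,
                            mode = c("within", "between", "indirect"),
                            fixed_set = NULL, n_trials = 5000,
                            universe = NULL, intermediates = NULL,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "between" && is.null(fixed_set)) {
    abort("between mode needs a fixed_set")
  }
  universe <- universe %||% network_nodes(net)
  test_set <- unique(test_set)
  observed <- observed_count(net, test_set, mode, fixed_set, intermediates)
  counts <- with_seed(seed, random_set_counts(
    net, test_set, mode, fixed_set, universe, n_trials, intermediates
  ))
  folds <- observed / pmax(counts, 1)
  structure(
    list(
      observed = observed,
      n_trials = n_trials,
      per_trial_counts = counts,
      per_trial_folds = folds,
      mean_fold = mean(folds),
      sd_fold = sd(folds),
      direction = if (mean(folds) >= 1) "enriched" else "depleted",
      floored_trials = sum(counts == 0),
      mode = mode,
      test_size = length(test_set),
      seed = seed
    ),
    class = "fold_diff"
  )
}

#' @export
print.fold_diff <- function(x, ...) {
  cat(sprintf(
    "<fold_diff: %s, |set|=%d, observed=%d, mean fold %.3f (sd %.3f), %s over %d trials%s>\n",
    x$mode, x$test_size, x$observed, x$mean_fold, x$sd_fold, x$direction,
    x$n_trials,
    if (x$floored_trials > 0) sprintf(", %d floored", x$floored_trials) else ""
  ))
  invisible(x)
}

#' Monte-Carlo p-value for an edge-count test
#'
#' Runs `n_sims` random-set simulations (same null as [fold_difference()]),
#' counts how many random sets are at least as extreme as the observed count
#' (`>=` for the enriched tail, `<=` for depleted), and reports the upper
#' bound of the exact Clopper-Pearson binomial confidence interval for that
#' exceedance proportion as the p-value.
#'
#' @inheritParams fold_difference
#' @param observed Observed count; computed from the network when `NULL`.
#' @param n_sims Number of simulations (default 100,000).
#' @param ci_level Confidence level of the binomial interval (0.9999 for the
#'   PPI tests, 0.95 for the regulatory-network tests).
#' @param tail `"enriched"` or `"depleted"`.
#' @return An `mc_pvalue` object (`p_value`, `n_as_extreme`, `n_sims`,
#'   `ci_level`, `tail`, `observed`).
#' @export
mc_pvalue <- function(net, test_set,
                      mode = c("within", "between", "indirect"),
                      fixed_set = NULL, observed = NULL, n_sims = 1e5,
                      ci_level = 0.9999, tail = c("enriched", "depleted"),
                      universe = NULL, intermediates = NULL, seed = NULL) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  stopifnot(n_sims >= 1)
  universe <- universe %||% network_nodes(net)
  test_set <- unique(test_set)
  observed <- observed %||%
    observed_count(net, test_set, mode, fixed_set, intermediates)
  counts <- with_seed(seed, random_set_counts(
    net, test_set, mode, fixed_set, universe, n_sims, intermediates
  ))
  n_extreme <- if (tail == "enriched") {
    sum(counts >= observed)
  } else {
    sum(counts <= observed)
  }
  structure(
    list(
      observed = observed,
      n_sims = n_sims,
      n_as_extreme = n_extreme,
      ci_level = ci_level,
      tail = tail,
      p_value = cp_upper(n_extreme, n_sims, ci_level),
      seed = seed
    ),
    class = "mc_pvalue"
  )
}

#' @export
print.mc_pvalue <- function(x, ...) {
  cat(sprintf(
    "<mc_pvalue: observed=%d, %d/%d as extreme (%s), p <= %.3g at CI %.4f>\n",
    x$observed, x$n_as_extreme, x$n_sims, x$tail, x$p_value, x$ci_level
  ))
  invisible(x)
}
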