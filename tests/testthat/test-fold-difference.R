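test_that("Clopper-Pearson upper bounds match the closed form and binom.test", {
  # zero successes: 1 - (alpha/2)^(1/n)
  n <- 1e5
  expect_equal(
    pmaxnet:::cp_upper(0, n, 0.9999),
    1 - (1e-4 / 2)^(1 / n),
    tolerance = 1e-12
  )
  expect_equal(pmaxnet:::cp_upper(0, n, 0.9999), 9.90e-5, tolerance = 1e-3)
  expect_equal(pmaxnet:::cp_upper(5, 5, 0.95), 1)
  # independent check against stats::binom.test for interior cases
  for (x in c(1, 7, 42)) {
    expect_equal(
      pmaxnet:::cp_upper(x, 100, 0.95),
      binom.test(x, 100, conf.level = 0.95)$conf.int[2],
      tolerance = 1e-10
    )
  }
})

test_that("a test set with no internal edges has zero mean fold", {
  net <- net_from_string("a-b,c-d,e-f,g-h")
  f <- fold_difference(net, c("a", "c"), "within", n_trials = 50, seed = 1)
  expect_equal(f$observed, 0)
  expect_equal(f$mean_fold, 0)
  expect_equal(f$direction, "depleted")
})

test_that("random-set means and exceedance match exhaustive enumeration", {
  net <- twelve_node_net()
  nodes <- network_nodes(net)
  test_set <- nodes[1:4]
  pool <- setdiff(nodes, test_set)
  oracle <- exhaustive_within_stats(
    net, pool, 4,
    observed = count_edges_within(net, test_set)
  )

  f <- fold_difference(net, test_set, "within", n_trials = 2000, seed = 8)
  se <- oracle$sd / sqrt(f$n_trials)
  expect_lt(abs(mean(f$per_trial_counts) - oracle$mean), 3 * se)

  p <- mc_pvalue(net, test_set, "within", n_sims = 4000, seed = 9,
                 tail = "enriched", ci_level = 0.95)
  frac <- p$n_as_extreme / p$n_sims
  se_p <- sqrt(oracle$exceed_ge * (1 - oracle$exceed_ge) / p$n_sims)
  expect_lt(abs(frac - oracle$exceed_ge), 3 * se_p + 1e-9)
})

test_that("fold summaries are consistent with the per-trial lists", {
  net <- twelve_node_net()
  f <- fold_difference(net, network_nodes(net)[1:4], "within",
                       n_trials = 300, seed = 5)
  expect_length(f$per_trial_folds, 300)
  expect_equal(f$mean_fold, mean(f$per_trial_folds), tolerance = 1e-9)
  expect_equal(f$sd_fold, sd(f$per_trial_folds), tolerance = 1e-9)
  expect_equal(f$floored_trials, sum(f$per_trial_counts == 0))
  g <- glance(f)
  expect_equal(g$mean_fold, f$mean_fold)
  td <- tidy(f)
  expect_equal(nrow(td), 300)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("an exchangeable test set converges to fold 1", {
  set.seed(31)
  nodes <- paste0("v", 1:60)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.15
  net <- as_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
  test_set <- sample(network_nodes(net), 15)
  f <- fold_difference(net, test_set, "within", n_trials = 3000, seed = 2)
  expect_lt(abs(f$mean_fold - 1), 3 * f$sd_fold / sqrt(3000) * 50)
})

test_that("mc_pvalue is monotone in the observed count for the enriched tail", {
  net <- twelve_node_net()
  test_set <- network_nodes(net)[1:4]
  ps <- vapply(0:4, function(obs) {
    mc_pvalue(net, test_set, "within", observed = obs, n_sims = 500,
              seed = 77, ci_level = 0.95)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("null-model p-values are calibrated on structureless networks", {
  # with no planted structure the exceedance fractions should not be
  # anti-conservative: the CP bound keeps p above the raw fraction
  set.seed(12)
  nodes <- paste0("v", 1:40)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.2
  net <- as_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
  ps <- vapply(1:200, function(s) {
    test_set <- withr::with_seed(s, sample(network_nodes(net), 8))
    mc_pvalue(net, test_set, "within", n_sims = 120, seed = s + 1000,
              ci_level = 0.95)$p_value
  }, numeric(1))
  frac_small <- mean(ps < 0.05)
  expect_lte(frac_small, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("infeasible random draws are rejected", {
  net <- net_from_string("a-b,c-d")
  expect_error(
    fold_difference(net, c("a", "b", "c"), "within", n_trials = 5),
    "universe too small"
  )
  expect_error(fold_difference(net, "a", "between"), "fixed_set")
})

test_that("between-mode folds use only cross edges to the fixed set", {
  net <- net_from_string("a-x,a-y,b-x,c-d,e-f,g-h,i-j")
  f <- fold_difference(net, c("a", "b"), "between", fixed_set = c("x", "y"),
                       n_trials = 100, seed = 3)
  expect_equal(f$observed, 3)
})
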