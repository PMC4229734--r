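ctx_fixture <- function() {
  expr <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    brain = c(90, 60, 0, 0.4),
    eye = c(100, 100, 100, 100)
  )
  list(
    expr = expr,
    es = compute_specificity(expr),
    pm = compute_pmax(expr),
    # e is in the network but has no expression data
    net = net_from_string("a-b,b-c,a-e,c-d")
  )
}

test_that("context networks drop genes below the expression floor", {
  fx <- ctx_fixture()
  # c has Es = 0 in brain -> excluded; e has no data, retained by default
  ctx <- context_network(fx$net, fx$es, "brain", "tissue")
  expect_false("c" %in% network_nodes(ctx))
  expect_true("e" %in% network_nodes(ctx))
  # drop policy removes no-data genes too
  ctx2 <- context_network(fx$net, fx$es, "brain", "tissue",
                          missing_policy = "drop")
  expect_false("e" %in% network_nodes(ctx2))
  # stage regime applies the 0.005 Es floor: d has brain Es 0.4/100.4 > 0.005
  # in brain but c is exactly 0 -> still excluded
  ctx3 <- context_network(fx$net, fx$es, "eye", "tissue")
  expect_equal(nrow(ctx3), nrow(fx$net))
  expect_error(context_network(fx$net, fx$es, "wing", "tissue"), "wing")
})

test_that("stage context networks apply the strict 0.005 floor", {
  expr <- tibble::tibble(
    gene = c("lo", "hi"), s1 = c(0.4, 10), s2 = c(99.6, 90)
  )
  es <- compute_specificity(expr)  # lo: s1 Es = 0.004
  net <- net_from_string("lo-hi")
  expect_equal(nrow(context_network(net, es, "s1", "stage")), 0)
  expect_equal(nrow(context_network(net, es, "s2", "stage")), 1)
})

test_that("pmax gene lists use a strict threshold and need data", {
  fx <- ctx_fixture()
  # brain pmax: a=90, b=60, c=0, d=0.4; e has no data
  expect_setequal(
    pmax_filter_genes(c("a", "b", "c", "e"), fx$pm, "brain", 50), c("a", "b")
  )
  expect_setequal(
    pmax_filter_genes(c("a", "b", "c", "e"), fx$pm, "brain", 65), "a"
  )
  # boundary: pmax exactly at the threshold is excluded
  expect_length(pmax_filter_genes("a", fx$pm, "brain", 90), 0)
  expect_setequal(pmax_filter_genes("a", fx$pm, "brain", 89.9), "a")
  # pmax 100 passes any threshold below 100
  expect_setequal(pmax_filter_genes(fx$expr$gene, fx$pm, "eye", 99),
                  c("a", "b", "c", "d"))
  expect_error(pmax_filter_genes("a", fx$pm, "brain", 0), "threshold")
})

test_that("pmax network filtering keeps edges between passing genes only", {
  fx <- ctx_fixture()
  # threshold 75 in brain: a passes (90), b fails (60) -> a-b removed, and a
  # keeps only its edge to the no-data gene e under the retain policy
  res <- pmax_filter_network(fx$net, fx$pm, "brain", 75)
  expect_setequal(paste(res$network$from, res$network$to), "a e")
  expect_equal(res$report$genes_passing, 1)
  expect_equal(res$report$genes_retained_missing, 1)
  expect_equal(res$report$genes_in_subnetwork, 2)

  # drop policy removes the no-data gene, emptying the subnetwork
  res2 <- pmax_filter_network(fx$net, fx$pm, "brain", 75,
                              missing_policy = "drop")
  expect_equal(nrow(res2$network), 0)
  expect_equal(res2$report$genes_in_subnetwork, 0)
  expect_lte(
    res2$report$genes_in_subnetwork,
    res2$report$genes_passing
  )

  # passing genes left without a passing partner drop out as isolated
  res3 <- pmax_filter_network(fx$net, fx$pm, "brain", 30,
                              missing_policy = "drop")
  # a (90) and b (60) pass and are connected; c,d fail; e dropped
  expect_setequal(network_nodes(res3$network), c("a", "b"))
  expect_gte(res3$report$dropped_isolated, 0)
})

test_that("raising the pmax threshold never grows the subnetwork", {
  cfg <- sim_config(n_genes = 400, mean_degree = 8, seed = 13)
  sim <- simulate_expression_matrix(cfg, "tissue")
  net <- simulate_ppi_network(sim$truth, cfg)$network
  pm <- compute_pmax(sim$expression)
  cond <- "tissue_01"
  reports <- lapply(c(25, 45, 50, 65, 75, 85), function(th) {
    pmax_filter_network(net, pm, cond, th)$report
  })
  nodes <- vapply(reports, function(r) r$genes_in_subnetwork, numeric(1))
  edges <- vapply(reports, function(r) r$edges_in_subnetwork, numeric(1))
  expect_true(all(diff(nodes) <= 0))
  expect_true(all(diff(edges) <= 0))
  # a vanishing threshold with retain policy recovers the context network
  res0 <- pmax_filter_network(net, pm, cond, 1e-9)
  es <- compute_specificity(sim$expression)
  ctx <- context_network(net, es, cond, "tissue")
  expect_equal(nrow(res0$network), nrow(ctx))
})

test_that("average-expression filter keeps strictly above-mean genes", {
  expr <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    t = c(1, 2, 3, 10)
  )
  expect_equal(average_expression_filter(expr$gene, expr, "t"), "g4")
  flat <- tibble::tibble(gene = c("a", "b"), t = c(5, 5))
  expect_length(average_expression_filter(flat$gene, flat, "t"), 0)
  single <- tibble::tibble(gene = "a", t = 3)
  expect_length(average_expression_filter("a", single, "t"), 0)
})
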