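test_that("Es is the per-gene fraction of total abundance", {
  expr <- tibble::tibble(
    gene = c("u", "s", "m"),
    a = c(10, 5, 2), b = c(10, 0, 3), c = c(10, 0, 5), d = c(10, 0, 0)
  )
  es <- compute_specificity(expr)
  get <- function(g) es$es[es$gene == g]
  expect_equal(get("u"), rep(0.25, 4))
  expect_equal(get("s"), c(1, 0, 0, 0))
  expect_equal(get("m"), c(0.2, 0.3, 0.5, 0))
})

test_that("Es values sum to 1 for every gene with positive total", {
  set.seed(44)
  expr <- tibble::tibble(
    gene = sprintf("g%03d", 1:80),
    as.data.frame(matrix(rexp(80 * 6), 80, 6))
  )
  es <- compute_specificity(expr)
  sums <- tapply(es$es, es$gene, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("zero-total and missing-cell genes are flagged, not fatal", {
  expr <- tibble::tibble(gene = c("z", "m"), a = c(0, NA), b = c(0, NA))
  es <- compute_specificity(expr)
  expect_setequal(attr(es, "degenerate_genes"), c("z", "m"))
  expect_true(all(is.na(es$es)))
  pm <- compute_pmax(expr)
  expect_setequal(attr(pm, "degenerate_genes"), c("z", "m"))
  expect_true(all(is.na(pm$pmax)))
})

test_that("pmax rescales each gene to percent of its maximum", {
  expr <- tibble::tibble(
    gene = c("g", "const"), a = c(50, 7), b = c(100, 7), c = c(25, 7)
  )
  pm <- compute_pmax(expr)
  expect_equal(pm$pmax[pm$gene == "g"], c(50, 100, 25))
  expect_equal(pm$pmax[pm$gene == "const"], c(100, 100, 100))
  expect_equal(unique(pm$max_condition[pm$gene == "g"]), "b")
})

test_that("missing cells are excluded from the pmax maximum", {
  expr <- tibble::tibble(gene = "g", a = NA_real_, b = 10, c = 5)
  pm <- compute_pmax(expr)
  expect_equal(pm$pmax, c(NA, 100, 50))
  expect_equal(unique(pm$max_condition), "b")
})

test_that("Es and pmax are invariant to per-gene rescaling", {
  set.seed(7)
  expr <- tibble::tibble(
    gene = sprintf("g%02d", 1:30),
    as.data.frame(matrix(rexp(30 * 5), 30, 5))
  )
  k <- runif(30, 0.01, 100)
  scaled <- expr
  scaled[, -1] <- expr[, -1] * k
  expect_equal(compute_specificity(scaled)$es, compute_specificity(expr)$es)
  expect_equal(compute_pmax(scaled)$pmax, compute_pmax(expr)$pmax)
})

test_that("classification applies cutoffs, floors, and tie-breaks", {
  # tissue: specific at Es >= 0.8; ubiquitous needs non-zero everywhere
  expr <- tibble::tibble(
    gene = c("spec", "ubiq", "nuns"),
    t1 = c(85, 30, 10), t2 = c(15, 35, 0), t3 = c(0, 35, 5)
  )
  cl <- classify_genes(compute_specificity(expr), "tissue")
  expect_equal(cl$class[cl$gene == "spec"], "specific")
  expect_equal(cl$condition[cl$gene == "spec"], "t1")
  expect_equal(cl$class[cl$gene == "ubiq"], "ubiquitous")
  expect_equal(cl$class[cl$gene == "nuns"], "NUNS")

  # stage: the 0.005 floor is strict; no stage reaches the 0.19 cutoff
  stage <- tibble::tibble(gene = "g", !!!stats::setNames(
    as.list(c(0.004, rep(0.996 / 9, 9))), sprintf("s%02d", 1:10)
  ))
  cls <- classify_genes(compute_specificity(stage), "stage")
  expect_equal(cls$class, "NUNS")

  # tie for the specific condition breaks to the first condition label
  tie <- tibble::tibble(gene = "g", zb = 50, za = 50)
  clt <- classify_genes(
    compute_specificity(tie),
    classification_thresholds("tissue", specific_cutoff = 0.5)
  )
  expect_equal(clt$condition, "za")
})

test_that("classification is invariant to rescaling and column order", {
  set.seed(11)
  cfg <- sim_config(n_genes = 150, seed = 11)
  expr <- simulate_expression_matrix(cfg, "tissue")$expression
  base <- classify_genes(compute_specificity(expr), "tissue")
  scaled <- expr
  scaled[, -1] <- scaled[, -1] * runif(nrow(expr), 0.1, 10)
  expect_equal(classify_genes(compute_specificity(scaled), "tissue"), base)
  shuffled <- expr[, c(1, sample(2:ncol(expr)))]
  expect_equal(classify_genes(compute_specificity(shuffled), "tissue"), base)
})

test_that("replicate collapse keeps all-present cells only", {
  raw <- tidyr::expand_grid(
    gene = "g1", condition = c("a", "b"), replicate = 1:4
  )
  raw$signal <- c(4, 6, 8, 10, 1, 1, 1, 1)
  raw$call <- c(rep("present", 4), "present", "absent", "present", "present")
  expr <- preprocess_replicates(raw, 4)
  expect_equal(expr$a, 7)
  expect_true(is.na(expr$b))
  expect_error(preprocess_replicates(raw, 3), "replicates")
})

test_that("threshold validation rejects inconsistent cutoffs", {
  expect_error(classification_thresholds("tissue", specific_cutoff = 0), "cutoff")
  expect_error(
    classification_thresholds("tissue", ubiquitous_floor = 0.9),
    "cutoff"
  )
})
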