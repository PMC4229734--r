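test_that("hypergeometric tails match hand-computed and enumerated values", {
  bg <- paste0("g", 1:10)
  ann <- annotation_set(list(t1 = bg[1:5]), bg)
  res <- term_enrichment(bg[1:4], ann, tail = "enriched")
  # all four query genes annotated: C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(res$p_raw, 5 / 210, tolerance = 1e-12)
  expect_equal(res$k, 4)
  expect_equal(res$fold, (4 / 4) / (5 / 10))

  # brute-force enumeration over all draws for several configurations
  for (case in list(c(N = 10, K = 5, n = 4, k = 4),
                    c(N = 12, K = 3, n = 5, k = 1),
                    c(N = 9, K = 4, n = 3, k = 2))) {
    N <- case["N"]; K <- case["K"]; n <- case["n"]; k <- case["k"]
    expect_equal(
      unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE)),
      brute_hyper_tail(N, K, n, k, "enriched"),
      tolerance = 1e-12
    )
    expect_equal(
      unname(phyper(k, K, N - K, n, lower.tail = TRUE)),
      brute_hyper_tail(N, K, n, k, "depleted"),
      tolerance = 1e-12
    )
  }
})

test_that("a count at its expectation is not enriched", {
  bg <- paste0("g", 1:20)
  ann <- annotation_set(list(t1 = bg[1:10]), bg)
  res <- term_enrichment(bg[c(1, 2, 11, 12)], ann, tail = "enriched")
  expect_gte(res$p_raw, 0.5)
})

test_that("multiple-testing corrections behave as documented", {
  bg <- paste0("g", 1:30)
  set.seed(2)
  terms <- lapply(1:8, function(i) sample(bg, 10))
  names(terms) <- paste0("t", 1:8)
  ann <- annotation_set(terms, bg)
  query <- bg[1:10]
  bonf <- term_enrichment(query, ann, correction = "bonferroni")
  bh <- term_enrichment(query, ann, correction = "bh")
  m <- nrow(bonf)
  expect_equal(bonf$p_corrected, pmin(1, m * bonf$p_raw))
  # BH never exceeds Bonferroni and preserves the p_raw order
  j <- dplyr::left_join(
    dplyr::select(bh, term, p_raw, bh = p_corrected),
    dplyr::select(bonf, term, bonf = p_corrected),
    by = "term"
  )
  expect_true(all(j$bh <= j$bonf + 1e-12))
  expect_false(is.unsorted(bh$p_corrected))
  expect_true(all(bh$p_corrected >= bh$p_raw - 1e-12))

  one <- annotation_set(terms[1], bg)
  r1b <- term_enrichment(query, one, correction = "bonferroni")
  r1h <- term_enrichment(query, one, correction = "bh")
  expect_equal(r1b$p_corrected, r1b$p_raw)
  expect_equal(r1h$p_corrected, r1h$p_raw)
})

test_that("enrichment of a term mirrors depletion of its complement", {
  bg <- paste0("g", 1:15)
  term <- bg[1:6]
  ann_t <- annotation_set(list(t = term), bg)
  ann_c <- annotation_set(list(comp = setdiff(bg, term)), bg)
  query <- bg[c(1:4, 7, 8)]
  p_enr <- term_enrichment(query, ann_t, tail = "enriched")$p_raw
  p_dep <- term_enrichment(query, ann_c, tail = "depleted")$p_raw
  expect_equal(p_enr, p_dep, tolerance = 1e-12)
})

test_that("degenerate inputs are handled", {
  bg <- paste0("g", 1:10)
  empty <- annotation_set(list(), bg)
  expect_equal(nrow(term_enrichment(bg[1:3], empty)), 0)
  ann <- annotation_set(list(t1 = bg[1:3]), bg)
  expect_message(
    res <- term_enrichment(c(bg[1:3], "zz"), ann),
    "not in background"
  )
  expect_equal(res$n, 3)
  expect_error(annotation_set(list(t = "zz"), bg), "background")
  expect_error(term_enrichment("a", annotation_set(list(), character(0))), "background")
})

test_that("uniform terms are calibrated and planted terms recovered", {
  cfg <- sim_config(n_genes = 600, n_terms = 30, planted_term_fold = 10,
                    term_size = c(40L, 80L), seed = 35)
  sim <- simulate_expression_matrix(cfg, "tissue")
  ann <- simulate_annotations(sim$truth, cfg)
  planted <- ann$planted
  expect_gt(nrow(planted), 0)
  # query: genes specific to the first planted condition
  cond <- planted$condition[1]
  query <- sim$truth$gene[
    sim$truth$class == "specific" & !is.na(sim$truth$condition) &
      sim$truth$condition == cond
  ]
  res <- term_enrichment(query, ann$annotations, correction = "bonferroni")
  expect_true(planted$term[1] %in% res$term[1:3])

  # calibration: on uniform random queries the raw p-values are not
  # anti-conservative (hypergeometric discreteness makes this <=)
  set.seed(101)
  fracs <- replicate(40, {
    q <- sample(sim$truth$gene, 60)
    r <- term_enrichment(q, ann$annotations)
    mean(r$p_raw < 0.05)
  })
  expect_lte(mean(fracs), 0.05 + 3 * sqrt(0.05 * 0.95 / (40 * 30)))
})

test_that("GMT files round-trip", {
  bg <- paste0("g", 1:10)
  ann <- annotation_set(list(t1 = bg[1:3], t2 = bg[4:9]), bg)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path, background = bg)
  expect_equal(back$terms, ann$terms)
  writeLines("short\tonly", path)
  expect_error(read_gmt(path), "fewer than 3")
})
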