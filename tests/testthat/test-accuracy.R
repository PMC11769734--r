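test_that("empirical AUROC matches hand-computed Mann-Whitney values", {
  expect_equal(empirical_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(empirical_auroc(rep(5, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  # 6 positive-negative pairs, one tie at half credit -> 11/12
  expect_equal(empirical_auroc(c(3, 1, 2, 4, 2), c(1, 0, 0, 1, 1)), 11 / 12)
  expect_error(empirical_auroc(1:4, c(1, 1, 1, 1)),
               class = "pairedmrmc_degenerate_error")
})

test_that("AUROC agrees with trapezoidal and pair-counting oracles on random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- sample(0:20, n, replace = TRUE) # heavy ties on purpose
    a <- empirical_auroc(scores, labels)
    expect_equal(a, trapezoid_auroc(scores, labels), tolerance = 1e-12)
    if (i <= 50) expect_equal(a, paircount_auroc(scores, labels),
                              tolerance = 1e-12)
    if (i <= 20) expect_equal(a, as.numeric(suppressMessages(
      pROC::auc(labels, scores, direction = "<"))), tolerance = 1e-12)
  }
})

test_that("AUROC reflection and monotone-transform invariance hold", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq_len(1000), n)  # tie-free
    expect_equal(empirical_auroc(scores, labels) +
                   empirical_auroc(-scores, labels), 1)
    expect_equal(empirical_auroc(exp(scores / 300), labels),
                 empirical_auroc(scores, labels))
  }
})

test_that("positivity rules binarize categories as specified", {
  p3 <- positivity_rule("p3"); p4 <- positivity_rule("p4")
  p4psad <- positivity_rule("p4psad")
  expect_false(apply_positivity_rule(3, 0.14, p4psad))
  expect_true(apply_positivity_rule(3, 0.15, p4psad))  # inclusive threshold
  expect_true(apply_positivity_rule(5, NA, p4))
  expect_equal(apply_positivity_rule(c(2, 3, 4, 5), 0.2, p3),
               c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(apply_positivity_rule(3, NA, p4psad), "PSAd")
  expect_error(apply_positivity_rule(1, 0.2, p3),
               class = "pairedmrmc_domain_error")
})

test_that("sensitivity and specificity match enumeration on the 4-case fixture", {
  cats <- c(2, 3, 4, 5); labels <- c(0, 1, 0, 1); psad <- rep(0.2, 4)
  expect_equal(sens_spec(cats, psad, labels, positivity_rule("p3")),
               c(sensitivity = 1.0, specificity = 0.5))
  # P4 misses the category-3 positive: sens 0.5; calls the category-4
  # negative: spec 0.5
  expect_equal(sens_spec(cats, psad, labels, positivity_rule("p4")),
               c(sensitivity = 0.5, specificity = 0.5))
  expect_equal(sens_spec(rep(2, 4), psad, labels, positivity_rule("p3")),
               c(sensitivity = 0, specificity = 1))
  expect_error(sens_spec(cats, psad, c(1, 1, 1, 1), positivity_rule("p3")),
               class = "pairedmrmc_degenerate_error")
})

test_that("nested positivity rules order sensitivity and specificity monotonically", {
  st <- small_sim(seed = 5)
  rules <- list(positivity_rule("p3"), positivity_rule("p4psad"),
                positivity_rule("p4"))
  sens <- lapply(rules, function(r)
    per_reader_metric_table(st, "sensitivity", r)$value)
  spec <- lapply(rules, function(r)
    per_reader_metric_table(st, "specificity", r)$value)
  expect_true(all(sens[[1]] >= sens[[2]] - 1e-12))
  expect_true(all(sens[[2]] >= sens[[3]] - 1e-12))
  expect_true(all(spec[[1]] <= spec[[2]] + 1e-12))
  expect_true(all(spec[[2]] <= spec[[3]] + 1e-12))
})

test_that("per-reader tables are paired, in range, and match hand-computed AUROCs", {
  # identical modalities -> identical columns
  st <- make_tiny_study(mp_offset = 0)
  tab <- per_reader_metric_table(st, "auroc")
  wide <- split(tab$value, tab$modality)
  expect_equal(wide$bp, wide$mp)

  # hand fixture: 2 readers x 4 cases with known Mann-Whitney values
  s1 <- c(10, 40, 30, 80); s2 <- c(50, 20, 60, 70)
  labels <- c(0, 1, 0, 1)
  st2 <- make_tiny_study(n_blocks = 1, readers_per_block = 2,
                         labels = labels, suspicion = s1)
  st2$readings$suspicion[st2$readings$reader_id == "r1_2"] <-
    rep(s2, 2)
  tab2 <- per_reader_metric_table(st2, "auroc")
  expect_equal(tab2$value[tab2$reader_id == "r1_1"],
               rep(paircount_auroc(s1, labels), 2))
  expect_equal(tab2$value[tab2$reader_id == "r1_2"],
               rep(paircount_auroc(s2, labels), 2))

  # simulator output: one value per (modality, reader), all within [0, 1]
  st3 <- small_sim(seed = 9)
  tab3 <- per_reader_metric_table(st3, "auroc")
  expect_equal(nrow(tab3), 2 * nrow(st3$readers))
  expect_true(all(tab3$value >= 0 & tab3$value <= 1))
})
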