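sub_df <- function(scores, labels, cats = NULL, psad = 0.2) {
  data.frame(case_id = sprintf("c%02d", seq_along(scores)),
             suspicion = scores,
             patient_pirads = if (is.null(cats)) rep(4, length(scores)) else cats,
             label = labels, psad = psad, stringsAsFactors = FALSE)
}

test_that("leave-one-out jackknife matches brute-force recomputation", {
  scores <- c(15, 42, 37, 88); labels <- c(0, 1, 0, 1)
  jk <- jackknife_accuracies(sub_df(scores, labels), "auroc")
  for (k in seq_along(scores))
    expect_equal(unname(jk[k]), paircount_auroc(scores[-k], labels[-k]))

  # larger tied instance against the independent pair-counting oracle
  set.seed(3)
  scores <- sample(0:15, 20, replace = TRUE)
  labels <- c(0, 1, rbinom(18, 1, 0.4))
  jk <- jackknife_accuracies(sub_df(scores, labels), "auroc")
  for (k in seq_along(scores))
    expect_equal(unname(jk[k]), paircount_auroc(scores[-k], labels[-k]))
})

test_that("jackknife of a constant metric has zero variance and sens ignores negatives", {
  # every positive called positive -> sensitivity 1 in every LOO sample
  cats <- c(4, 4, 4, 2, 2, 4); labels <- c(1, 1, 1, 0, 0, 1)
  jk <- jackknife_accuracies(sub_df(seq(10, 60, 10), labels, cats),
                             "sensitivity")
  expect_equal(unname(jk), rep(1, 6))

  # deleting a negative case leaves sensitivity unchanged
  cats <- c(4, 2, 3, 2, 5); labels <- c(1, 1, 0, 0, 1)
  full <- sens_spec(cats, 0.2, labels, positivity_rule("p3"))[["sensitivity"]]
  jk <- jackknife_accuracies(sub_df(seq(10, 50, 10), labels, cats),
                             "sensitivity")
  expect_equal(unname(jk[labels == 0]), rep(full, 2))
})

test_that("covariance components equal the definitional brute-force computation", {
  set.seed(21)
  labels <- c(1, 0, 1, 0, 1, 0)
  st <- make_tiny_study(n_blocks = 1, readers_per_block = 2, labels = labels)
  st$readings$suspicion <- sample(0:100, nrow(st$readings), replace = TRUE)
  tab <- per_reader_metric_table(st, "auroc")
  jk <- jackknife_study(st, "auroc")
  comps <- covariance_components(tab, jk)

  # oracle: brute-force LOO vectors and definitional pairwise covariances
  oracle_jk <- list()
  for (key in names(jk)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- st$readings[st$readings$modality == parts[1] &
                         st$readings$reader_id == parts[2], ]
    oracle_jk[[key]] <- vapply(seq_len(nrow(sub)), function(k)
      paircount_auroc(sub$suspicion[-k], labels[-k]), numeric(1))
    expect_equal(unname(jk[[key]]), oracle_jk[[key]])
  }
  units <- names(oracle_jk)
  kinds <- list(var_error = c(), cov1 = c(), cov2 = c(), cov3 = c())
  for (a in seq_along(units)) for (b in a:length(units)) {
    pa <- strsplit(units[a], ".", fixed = TRUE)[[1]]
    pb <- strsplit(units[b], ".", fixed = TRUE)[[1]]
    kind <- if (a == b) "var_error"
      else if (pa[2] == pb[2]) "cov1"
      else if (pa[1] == pb[1]) "cov2" else "cov3"
    kinds[[kind]] <- c(kinds[[kind]],
                       jk_cov_oracle(oracle_jk[[units[a]]], oracle_jk[[units[b]]]))
  }
  blk <- comps$blocks[[1]]
  for (kind in names(kinds))
    expect_equal(unname(blk$components[[kind]]), mean(kinds[[kind]]))

  # ms_tr against the two-way ANOVA definition
  th <- blk$theta
  resid <- sweep(sweep(th, 1, rowMeans(th)), 2, colMeans(th)) + mean(th)
  expect_equal(blk$ms_tr, sum(resid^2) / (ncol(th) - 1))
})

test_that("identical readings in both modalities collapse the difference variance", {
  st <- make_tiny_study(n_blocks = 1, readers_per_block = 3,
                        labels = c(0, 1, 0, 1, 1, 0),
                        suspicion = c(10, 70, 35, 80, 55, 20))
  st$readings$suspicion <- st$readings$suspicion +
    rep(c(0, 5, 9), each = 12)  # readers differ, modalities identical
  tab <- per_reader_metric_table(st, "auroc")
  comps <- covariance_components(tab, jackknife_study(st, "auroc"))
  blk <- comps$blocks[[1]]
  expect_equal(blk$components[["cov1"]], blk$components[["var_error"]])
  expect_equal(blk$components[["cov2"]], blk$components[["cov3"]])
  res <- or_test(pool_blocks(comps))
  expect_equal(res$diff, 0)
  expect_equal(res$ci_low, -res$ci_high)
})

test_that("independent reader scores give near-zero cross-reader covariances", {
  set.seed(55)
  labels <- rep(c(0, 1), 4)
  base <- make_tiny_study(n_blocks = 1, readers_per_block = 2,
                          labels = labels)
  c2 <- c3 <- numeric(500)
  for (i in 1:500) {
    st <- base
    st$readings$suspicion <- sample(0:100, nrow(st$readings), replace = TRUE)
    tab <- per_reader_metric_table(st, "auroc")
    comps <- covariance_components(tab, jackknife_study(st, "auroc"))
    c2[i] <- comps$blocks[[1]]$components[["cov2"]]
    c3[i] <- comps$blocks[[1]]$components[["cov3"]]
  }
  expect_lt(abs(mean(c2)), 3 * sd(c2) / sqrt(500) + 1e-8)
  expect_lt(abs(mean(c3)), 3 * sd(c3) / sqrt(500) + 1e-8)
})

test_that("noninferiority p-value is 0.5 at the margin and handles zero SE", {
  pooled <- list(mean_bp = 0.80, mean_mp = 0.85, diff = -0.05,
                 var_diff = 1e-4, se_diff = 0.01,
                 se_mean = c(bp = 0.01, mp = 0.01), ddf = 20, n_readers = 10)
  expect_equal(or_test(pooled, margin = 0.05)$p_noninf, 0.5)

  degenerate <- pooled; degenerate$se_diff <- 0
  expect_warning(res <- or_test(degenerate, margin = 0.05), "margin")
  expect_equal(res$p_noninf, 0.5)

  # interval always brackets the estimate; p in [0, 1]
  res2 <- or_test(pooled, margin = 0.05)
  expect_lte(res2$ci_low, res2$diff)
  expect_gte(res2$ci_high, res2$diff)
})

test_that("block pooling reduces to identity for one block and scales for replicates", {
  st <- small_sim(seed = 31)
  comps <- covariance_components(per_reader_metric_table(st, "auroc"),
                                 jackknife_study(st, "auroc"))
  one <- comps
  one$blocks <- comps$blocks[1]
  p1 <- pool_blocks(one)
  b1 <- comps$blocks[[1]]
  expect_equal(p1$mean_bp, b1$mean_bp)
  expect_equal(p1$diff, b1$mean_bp - b1$mean_mp)
  var_b1 <- (2 / b1$n_readers) *
    (b1$ms_tr + b1$n_readers *
       max(b1$components[["cov2"]] - b1$components[["cov3"]], 0))
  expect_equal(p1$se_diff, sqrt(var_b1))

  # four identical blocks: pooled mean = block mean, pooled se = block se / 2
  four <- comps
  four$blocks <- rep(comps$blocks[1], 4)
  names(four$blocks) <- paste0("B", 1:4)
  p4 <- pool_blocks(four)
  expect_equal(p4$mean_bp, b1$mean_bp)
  expect_equal(p4$se_diff, p1$se_diff / 2)
})

test_that("pooled estimates equal per-reader means under unequal block sizes", {
  st <- simulate_study(sim_config(n_readers = 14, n_cases = 60), seed = 13)
  expect_gt(length(unique(table(st$readers$block_id))), 1)  # unequal blocks
  res <- or_analysis(st, "auroc")
  tab <- attr(res, "table")
  bp <- tab$value[tab$modality == "bp"]
  mp <- tab$value[tab$modality == "mp"]
  expect_equal(res$mean_bp, mean(bp))
  expect_equal(res$mean_mp, mean(mp))
  expect_equal(res$diff, mean(bp - mp))  # unweighted per-reader differences
})
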