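test_that("simulated cases honor prevalence, block stratification and determinism", {
  cfg <- sim_config()
  cs <- simulate_cases(cfg, seed = 4)
  expect_equal(nrow(cs), 400)
  expect_equal(sum(cs$label), 133)  # round(0.3325 * 400)
  expect_equal(as.vector(table(cs$block_id)), rep(100, 4))
  # positives spread across blocks within one case
  expect_true(diff(range(tapply(cs$label, cs$block_id, sum))) <= 1)
  expect_true(all(cs$psad > 0) && all(cs$psa > 0) && all(cs$volume > 0))
  expect_true(all((cs$label == 1) == (cs$gg >= 2)))

  expect_identical(simulate_cases(cfg, seed = 4), cs)
  expect_false(identical(simulate_cases(cfg, seed = 5), cs))

  cfg0 <- sim_config(prevalence = 0)
  expect_true(all(simulate_cases(cfg0, seed = 1)$label == 0))
})

test_that("cutpoint calibration returns quantiles and flags infeasible targets", {
  cfg <- sim_config()
  set.seed(2)
  latent <- rnorm(4000)
  cuts <- calibrate_cutpoints(cfg, rep(0.25, 4), latent = latent)
  expect_equal(cuts, unname(quantile(latent, c(0.25, 0.5, 0.75))))

  all_neg <- sim_config(category_targets = c(1, 0, 0, 0))
  expect_true(all(is.infinite(all_neg$cutpoints)))
  st <- simulate_study(sim_config(n_readers = 4, n_cases = 20,
                                  category_targets = c(1, 0, 0, 0)), seed = 2)
  expect_true(all(st$readings$patient_pirads == 2))

  expect_error(calibrate_cutpoints(cfg, c(0.5, 0.5, 0.5, -0.5)),
               class = "pairedmrmc_calibration_error")
})

test_that("shared latent components make bp and mp identical when modality terms vanish", {
  cfg <- sim_config(n_readers = 8, n_cases = 40, delta = 0,
                    sigma2_mod_case = 0, sigma2_mod_reader = 0,
                    sigma2_error = 0)
  st <- simulate_study(cfg, seed = 6)
  fl <- concordance_flow(st)
  expect_equal(fl$concordant_fraction, 1)
  bp <- st$readings[st$readings$modality == "bp", ]
  mp <- st$readings[st$readings$modality == "mp", ]
  key <- paste(bp$reader_id, bp$case_id)
  mp <- mp[match(key, paste(mp$reader_id, mp$case_id)), ]
  expect_equal(bp$suspicion, mp$suspicion)
})

test_that("reading counts and reproducibility match the split-plot bookkeeping", {
  st <- simulate_study(sim_config(), seed = 3)
  expect_equal(nrow(st$readings), 12400)  # 62 readers x 100 cases x 2
  counts <- table(st$readings$reader_id)
  expect_true(all(counts == 200))

  st2 <- simulate_study(sim_config(n_readers = 8, n_cases = 40), seed = 5)
  expect_equal(nrow(st2$readings), 160)  # each of 8 readers: 10 cases x 2

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_study(simulate_study(sim_config(n_readers = 8, n_cases = 40),
                             seed = 9), dir1)
  write_study(simulate_study(sim_config(n_readers = 8, n_cases = 40),
                             seed = 9), dir2)
  for (f in c("readings.csv", "cases.csv", "readers.csv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("adding readers leaves existing case and reader draws untouched", {
  cfg8 <- sim_config(n_readers = 8, n_cases = 40)
  cfg12 <- sim_config(n_readers = 12, n_cases = 40)
  expect_identical(simulate_cases(cfg8, seed = 7), simulate_cases(cfg12, seed = 7))
  st8 <- simulate_study(cfg8, seed = 7)
  st12 <- simulate_study(cfg12, seed = 7)
  shared <- intersect(unique(st8$readings$reader_id),
                      unique(st12$readings$reader_id))
  expect_gt(length(shared), 0)
  n_same <- 0
  for (rid in shared) {
    r8 <- st8$readers[st8$readers$reader_id == rid, ]
    r12 <- st12$readers[st12$readers$reader_id == rid, ]
    # a reader keeps its draws whenever its allocation is unchanged
    if (r8$block_id == r12$block_id && r8$expertise == r12$expertise) {
      a <- st8$readings[st8$readings$reader_id == rid, ]
      b <- st12$readings[st12$readings$reader_id == rid, ]
      rownames(a) <- rownames(b) <- NULL
      expect_identical(a, b)
      n_same <- n_same + 1
    }
  }
  expect_gt(n_same, 0)
})

test_that("expertise deficit and modality effect move AUROC in the right direction", {
  st <- simulate_study(sim_config(), seed = 19)
  tab <- per_reader_metric_table(st, "auroc")
  exp_ids <- st$readers$reader_id[st$readers$expertise == "expert"]
  expect_gt(mean(tab$value[tab$reader_id %in% exp_ids]),
            mean(tab$value[!tab$reader_id %in% exp_ids]))

  cfg <- sim_config(n_readers = 20, n_cases = 200, delta = 0.4)
  st2 <- simulate_study(cfg, seed = 23)
  tab2 <- per_reader_metric_table(st2, "auroc")
  expect_gt(mean(tab2$value[tab2$modality == "mp"]),
            mean(tab2$value[tab2$modality == "bp"]))
})

test_that("the closed-form AUROC and the modality-effect calibration are consistent", {
  cfg <- sim_config()
  expect_equal(expected_auroc(cfg, "bp"), expected_auroc(cfg, "mp"))
  d <- calibrate_modality_effect(cfg, -0.03)
  cfg2 <- sim_config(delta = d)
  expect_equal(expected_auroc(cfg2, "bp") - expected_auroc(cfg2, "mp"),
               -0.03, tolerance = 1e-6)
  expect_gt(d, 0)
})
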