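test_that("generation is fully reproducible from the seed", {
  cfg <- simulation_config(n_classes = 30, seed = 1L)
  expect_identical(simulate_compounds(cfg), simulate_compounds(cfg))
  other <- simulate_compounds(simulation_config(n_classes = 30, seed = 2L))
  expect_false(identical(simulate_compounds(cfg), other))
  # the caller's RNG stream is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_compounds(cfg))
  expect_identical(runif(1), before)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_classes = 0),
    class = "woe_invalid_config")
  expect_error(simulation_config(hyperplasia_sensitivity = 1.5),
    class = "woe_invalid_config")
  expect_error(simulation_config(class_size = c(5, 2)),
    class = "woe_invalid_config")
  expect_error(
    simulation_config(n_classes = 3, carcinogen_prob = c(0.1, 0.9)),
    class = "woe_invalid_config"
  )
})

test_that("perfect sensitivity and specificity force a perfect stage 1", {
  cfg <- simulation_config(
    n_classes = 40, hyperplasia_sensitivity = 1,
    hyperplasia_fpr = 0, seed = 5L
  )
  sim <- simulate_compounds(cfg) |> categorize_histopathology()
  expect_gt(sum(sim$carcinogen), 0)
  expect_equal(unique(sim$cat_his[sim$carcinogen]), "TP")
  expect_equal(unique(sim$cat_his[!sim$carcinogen]), "TN")
})

test_that("small-sample category counts match the binomial oracle", {
  # expected cell counts are analytic functions of the configuration:
  # E[TP] = n p sens, E[FN] = n p (1 - sens), E[FP] = n (1-p) fpr
  cfg <- simulation_config(
    n_classes = 64, class_size = c(1L, 8L),
    carcinogen_prob = 0.44, hyperplasia_sensitivity = 0.24,
    hyperplasia_fpr = 0.12, seed = 17L
  )
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    cfg$seed <- 17L + i
    sim <- simulate_compounds(cfg) |> categorize_histopathology()
    c(
      sens = sum(sim$cat_his == "TP") / sum(sim$carcinogen),
      fpr = sum(sim$cat_his == "FP") / sum(!sim$carcinogen)
    )
  }, c(sens = 0, fpr = 0))
  mc_se <- apply(est, 1, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est["sens", ]) - 0.24), 3 * mc_se["sens"])
  expect_lt(abs(mean(est["fpr", ]) - 0.12), 3 * mc_se["fpr"])
})

test_that("stage-1 parameters are recovered at large n", {
  cfg <- simulation_config(
    n_classes = 2250, class_size = c(2L, 7L), seed = 31L
  )
  sim <- simulate_compounds(cfg) |> categorize_histopathology()
  n <- nrow(sim)
  expect_gt(n, 9000)
  n_carc <- sum(sim$carcinogen)
  sens_hat <- sum(sim$cat_his == "TP") / n_carc
  spec_hat <- sum(sim$cat_his == "TN") / (n - n_carc)
  se_sens <- sqrt(0.24 * 0.76 / n_carc)
  se_spec <- sqrt(0.88 * 0.12 / (n - n_carc))
  expect_lt(abs(sens_hat - cfg$hyperplasia_sensitivity), 3 * se_sens)
  expect_lt(abs(spec_hat - (1 - cfg$hyperplasia_fpr)), 3 * se_spec)

  # concordance of hyperplasia organ with a tumor organ tracks the
  # configured probability among hyperplasia-positive carcinogens
  cc <- organ_concordance(sim)
  tp <- cc$cat_his == "TP"
  conc_hat <- mean(cc$concordance[tp] == "concordant")
  se_conc <- sqrt(0.42 * 0.58 / sum(tp))
  expect_lt(abs(conc_hat - cfg$same_organ_prob), 3 * se_conc)
})

test_that("generated datasets pass vocabulary validation end to end", {
  sim <- simulate_compounds(simulation_config(n_classes = 15, seed = 3L))
  vocab <- test_kb()$vocabulary
  for (i in seq_len(nrow(sim))) {
    expect_no_error(parse_finding_list(sim$tumor_findings[i], vocab = vocab))
    expect_no_error(parse_finding_list(sim$hyperplasia_findings[i],
      with_morphology = FALSE, vocab = vocab))
  }
})
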