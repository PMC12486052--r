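test_that("the generator is seed-deterministic", {
  cfg <- sim_config(n_per_modality = 80)
  expect_identical(simulate_cohort(cfg, seed = 3), simulate_cohort(cfg, seed = 3))
  expect_false(identical(simulate_cohort(cfg, seed = 3),
                         simulate_cohort(cfg, seed = 4)))
})

test_that("null outcome model reproduces its base rate", {
  # with no treatment effect and no covariate effects, ORN is Bernoulli(p)
  cfg <- sim_config(n_per_modality = 1000,
                    outcome_model = list(base_rate = 0.05, effect = 0,
                                         link = "identity", beta = numeric(0)))
  co <- simulate_cohort(cfg, seed = 21)
  p_hat <- mean(co$orn)
  se <- sqrt(0.05 * 0.95 / nrow(co))
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("config validation catches infeasible parameters", {
  dm <- default_dose <- dvcforest:::default_dose_model()
  dm$VMAT$sd[1] <- -1
  expect_error(sim_config(dose_model = dm), "negative sd")
  expect_error(sim_config(confounding_modality = 2), "\\[0, 1\\]")
  expect_error(sim_config(outcome_model = list(link = "identity", effect = 1.5)),
               "risk difference")
})

test_that("ground-truth ATE equals the configured effect at the true threshold", {
  # identity-link betas must stay on the risk scale and keep p inside [0, 1]
  cfg <- sim_config(n_per_modality = 300,
                    outcome_model = list(link = "identity", base_rate = 0.1,
                                         effect = 0.25, factor = "V60Gy",
                                         threshold = 40,
                                         beta = c(dental_extraction = 0.1,
                                                  current_smoker = 0.08,
                                                  stage_iv = 0.08,
                                                  diabetes = 0.05)))
  gt <- ground_truth_ate(cfg, "V60Gy", 40, n_mc = 2e4, seed = 2)
  expect_equal(gt$ate, 0.25, tolerance = 1e-9)
  expect_equal(implied_tau(cfg, n_mc = 2e4, seed = 2)$ate, 0.25,
               tolerance = 1e-9)

  # zero effect: zero ATE at every threshold, for every factor
  cfg0 <- sim_config(outcome_model = list(effect = 0))
  for (thr in c(10, 40, 70)) {
    expect_equal(ground_truth_ate(cfg0, "V60Gy", thr, n_mc = 5000)$ate, 0)
  }
  expect_equal(ground_truth_ate(cfg0, "Dmean", 5000, n_mc = 5000)$ate, 0)
  expect_error(ground_truth_ate(cfg0, "V35Gy", 10), "unknown dosimetric factor")
})

test_that("logit-link ground truth is a Monte Carlo value with small error", {
  cfg <- sim_config()  # default logit model
  gt <- ground_truth_ate(cfg, "V60Gy", cfg$outcome_model$threshold,
                         n_mc = 4e5, seed = 9)
  expect_lt(gt$mc_se, 0.005)
  expect_gt(gt$ate, 0)      # positive log-odds effect => positive risk diff
  expect_lt(gt$ate, 0.2)    # rare outcome keeps the risk difference small
  # away from the true threshold the stochastic-intervention ATE attenuates
  gt_far <- ground_truth_ate(cfg, "V60Gy", cfg$outcome_model$threshold + 25,
                             n_mc = 4e5, seed = 9)
  expect_lt(gt_far$ate, gt$ate)
})

test_that("confounding biases the naive difference upward as constructed", {
  # covariates raise both dose burden and ORN risk, so the naive
  # difference-in-means at the true threshold overshoots the true effect
  cfg <- sim_config(n_per_modality = 30000, confounding_dose = 2,
                    outcome_model = list(link = "identity", base_rate = 0.08,
                                         effect = 0.2, factor = "V60Gy",
                                         threshold = 40,
                                         beta = c(dental_extraction = 0.25,
                                                  current_smoker = 0.2,
                                                  stage_iv = 0.2,
                                                  diabetes = 0.12)))
  co <- simulate_cohort(cfg, seed = 31)
  tv <- binarize(co, "V60Gy", 40)
  naive <- mean(co$orn[tv == 1]) - mean(co$orn[tv == 0])
  expect_gt(naive - 0.2, 0.02)
})

test_that("zero modality confounding gives exchangeable covariates", {
  # with confounding_modality = 0 both arms draw from the same marginals, so
  # per-covariate chi-square rejections at alpha = 0.05 stay near 5%
  reps <- 30
  rej <- 0
  tests <- 0
  for (r in seq_len(reps)) {
    co <- simulate_cohort(sim_config(n_per_modality = 335,
                                     confounding_modality = 0), seed = 500 + r)
    bt <- suppressWarnings(balance_tests(co))
    rej <- rej + sum(bt$p_value < 0.05)
    tests <- tests + nrow(bt)
  }
  expect_lt(rej / tests, 0.12)
})

test_that("YAML generator configs round-trip into sim_config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_per_modality = 50, confounding_dose = 0,
                        outcome_model = list(link = "identity",
                                             base_rate = 0.1, effect = 0.2,
                                             beta = list(diabetes = 0.05))),
                   f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_per_modality, 50)
  expect_equal(cfg$outcome_model$effect, 0.2)
  expect_equal(cfg$outcome_model$beta, c(diabetes = 0.05))
  expect_identical(simulate_cohort(cfg, seed = 2), simulate_cohort(cfg, seed = 2))
})

test_that("site-structured missingness matches the configured rates", {
  co <- simulate_cohort(sim_config(n_per_modality = 2000), seed = 12)
  vm <- co[co$modality == "VMAT", ]
  pb <- co[co$modality == "PBSPT", ]
  expect_equal(mean(vm$chemo == "MISSING"), 0.13, tolerance = 0.03)
  expect_equal(mean(pb$chemo == "MISSING"), 0.36, tolerance = 0.04)
  expect_identical(vm$chemo == "MISSING", vm$site == "B")
})
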