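test_that("optimal matching beats greedy on the classic 2x2 example", {
  scores <- c(0.1, 0.5, 0.45, 0.15)
  group <- c("VMAT", "VMAT", "PBSPT", "PBSPT")
  m <- match_optimal(scores, group, distance = "raw")
  expect_equal(attr(m, "total_distance"), 0.10, tolerance = 1e-12)
  got <- sort(paste(m$score_1, m$score_2))
  expect_equal(got, sort(c("0.1 0.15", "0.5 0.45")))
})

test_that("identical score multisets match at zero total distance", {
  s <- c(0.2, 0.4, 0.6, 0.2, 0.4, 0.6)
  g <- rep(c("VMAT", "PBSPT"), each = 3)
  m <- match_optimal(s, g, distance = "raw")
  expect_equal(attr(m, "total_distance"), 0, tolerance = 1e-12)
})

test_that("matching equals the brute-force assignment minimum on small instances", {
  set.seed(11)
  for (rep in 1:25) {
    na <- sample(2:6, 1)
    nb <- sample(na:7, 1)
    a <- runif(na)
    b <- runif(nb)
    m <- match_optimal(c(a, b), rep(c("VMAT", "PBSPT"), c(na, nb)),
                       distance = "raw")
    expect_equal(attr(m, "total_distance"), brute_force_match_total(a, b),
                 tolerance = 1e-10)
    expect_equal(nrow(m), min(na, nb))
    # each patient used at most once
    expect_false(anyDuplicated(m$id_1) > 0 || anyDuplicated(m$id_2) > 0)
  }
})

test_that("propensity scores average to the group fraction and are reproducible", {
  co <- test_cohort(n_per_arm = 400, seed = 8)
  ps <- estimate_propensity(co)
  expect_true(all(ps$propensity > 0 & ps$propensity < 1))
  expect_equal(mean(ps$propensity), mean(co$modality == "PBSPT"),
               tolerance = 1e-6)
  # duplicated covariate rows get identical scores
  co2 <- co
  co2[2, c("age", "tumor_stage", "gender", "chemo", "smoking_history",
           "current_smoker", "hypertension", "diabetes",
           "dental_extraction")] <-
    co[1, c("age", "tumor_stage", "gender", "chemo", "smoking_history",
            "current_smoker", "hypertension", "diabetes",
            "dental_extraction")]
  attr(co2, "schema") <- attr(co, "schema")
  ps2 <- estimate_propensity(co2)
  expect_equal(ps2$propensity[1], ps2$propensity[2], tolerance = 1e-10)
})

test_that("a covariate perfectly predicting modality raises a separation error", {
  co <- validate_cohort(mini_cohort_df())
  co$chemo <- ifelse(co$modality == "PBSPT", "yes", "no")
  attr(co, "schema") <- cohort_schema()
  expect_error(estimate_propensity(co), "separation.*chemo")
})

test_that("balance tests report p = 1 for perfectly balanced covariates", {
  df <- tibble::tibble(
    modality = rep(c("VMAT", "PBSPT"), each = 20),
    grp = rep(rep(c("a", "b"), each = 10), 2),  # contingency [[10,10],[10,10]]
    age = rep(c(60, 62, 64, 58), 10))           # identical in both groups
  bt <- balance_tests(df, covariates = c("grp", "age"))
  expect_equal(bt$statistic[bt$covariate == "grp"], 0)
  expect_equal(bt$p_value[bt$covariate == "grp"], 1)
  expect_equal(bt$statistic[bt$covariate == "age"], 0, tolerance = 1e-12)
  expect_equal(bt$p_value[bt$covariate == "age"], 1, tolerance = 1e-12)

  df$single <- "x"
  expect_warning(bt2 <- balance_tests(df, covariates = "single"),
                 "single level")
  expect_equal(bt2$p_value, 1)
})

test_that("matching repairs confounded between-group balance", {
  # imbalanced arms as in an unmatched registry: the modality-specific
  # covariate marginals make several chi-square tests reject sharply before
  # matching; 1:1 optimal matching on the propensity restores balance
  worked <- 0
  for (r in 1:5) {
    co <- simulate_cohort(
      sim_config(n_per_modality = c(VMAT = 900, PBSPT = 300)), seed = 700 + r)
    mc <- match_cohorts(co)
    expect_equal(nrow(mc$pairs), 300)
    expect_lt(min(mc$balance_before$p_value), 0.001)
    if (all(mc$balance_after$p_value > 0.05)) worked <- worked + 1
    # matching never increases the propensity-score SMD between groups
    ps <- mc$propensity
    smd_all <- pairwise_smd(ps$propensity[ps$modality == "VMAT"],
                            ps$propensity[ps$modality == "PBSPT"])
    kept <- ps[ps$patient_id %in% mc$matched_ids, ]
    smd_matched <- pairwise_smd(kept$propensity[kept$modality == "VMAT"],
                                kept$propensity[kept$modality == "PBSPT"])
    expect_lte(smd_matched, smd_all + 1e-9)
  }
  expect_gte(worked, 4)
})

test_that("matched cohort accessors expose a Table-2-style report", {
  co <- simulate_cohort(sim_config(n_per_modality = 120), seed = 77)
  mc <- match_cohorts(co)
  td <- tidy(mc)
  expect_named(td, c("covariate", "p_before", "p_after"))
  expect_equal(nrow(td), length(cohort_schema()$covariates))
  gl <- glance(mc)
  expect_equal(gl$n_pairs, 120)
})
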