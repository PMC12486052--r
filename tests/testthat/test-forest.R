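# -- R-side oracles -----------------------------------------------------------

# best split by exhaustive enumeration of every cut on every feature, scoring
# the size-weighted squared difference of child diff-in-means effects
oracle_best_split <- function(x, y, w, str, est, min_leaf) {
  tau_of <- function(idx) {
    wi <- w[idx]
    if (sum(wi == 1) == 0 || sum(wi == 0) == 0) return(NA_real_)
    mean(y[idx][wi == 1]) - mean(y[idx][wi == 0])
  }
  best <- list(score = 0, feature = NA_integer_, cut = NA_real_)
  for (f in seq_len(ncol(x))) {
    vals <- sort(unique(x[str, f]))
    if (length(vals) < 2) next
    cuts <- (head(vals, -1) + tail(vals, -1)) / 2
    for (cut in cuts) {
      sl <- str[x[str, f] <= cut]; sr <- str[x[str, f] > cut]
      el <- est[x[est, f] <= cut]; er <- est[x[est, f] > cut]
      arms <- function(idx) c(sum(w[idx] == 1), sum(w[idx] == 0))
      if (any(c(arms(sl), arms(sr), arms(el), arms(er)) < min_leaf)) next
      tl <- tau_of(sl); tr <- tau_of(sr)
      if (is.na(tl) || is.na(tr)) next
      score <- length(sl) * length(sr) / length(str)^2 * (tl - tr)^2
      if (score > best$score) best <- list(score = score, feature = f, cut = cut)
    }
  }
  best
}

leaf_id_of <- function(nodes, xrow) {
  id <- 1
  while (nodes[id, 1] > 0) {
    id <- if (xrow[nodes[id, 1]] <= nodes[id, 2]) nodes[id, 3] else nodes[id, 4]
  }
  id
}

forest_fixture <- function(n = 60, seed = 3) {
  set.seed(seed)
  tibble::tibble(x1 = rnorm(n), x2 = rnorm(n),
                 w = rbinom(n, 1, 0.5)) |>
    dplyr::mutate(orn = rbinom(n, 1, 0.25 + 0.4 * w * (x1 > 0)))
}

# -- tests --------------------------------------------------------------------

test_that("the root split matches the exhaustive heterogeneity oracle", {
  df <- forest_fixture(n = 60, seed = 3)
  cf <- causal_forest(df, df$w, covariates = c("x1", "x2"), n_trees = 5,
                      min_leaf = 2, mtry = 2, centering = "none",
                      seed = 11, keep_trees = TRUE)
  x <- cf$x
  checked <- 0
  for (tr in cf$trees) {
    nodes <- tr$nodes
    if (nodes[1, 1] == 0) next  # no valid root split in this subsample
    str <- setdiff(tr$subsample, tr$est_half)
    best <- oracle_best_split(x, cf$y, cf$w, str, tr$est_half, min_leaf = 2)
    expect_equal(nodes[1, 1], best$feature)
    expect_equal(nodes[1, 2], best$cut, tolerance = 1e-12)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("leaf effects come from the estimation half only (honest leaves)", {
  df <- forest_fixture(n = 80, seed = 5)
  cf <- causal_forest(df, df$w, covariates = c("x1", "x2"), n_trees = 10,
                      min_leaf = 3, mtry = 2, centering = "none",
                      seed = 2, keep_trees = TRUE)
  for (tr in cf$trees) {
    nodes <- tr$nodes
    if (nrow(nodes) < 3) next
    leaf_assign <- vapply(tr$est_half, function(i) leaf_id_of(nodes, cf$x[i, ]),
                          numeric(1))
    for (leaf in unique(leaf_assign)) {
      idx <- tr$est_half[leaf_assign == leaf]
      wi <- cf$w[idx]
      if (sum(wi == 1) == 0 || sum(wi == 0) == 0) next
      dim_est <- mean(cf$y[idx][wi == 1]) - mean(cf$y[idx][wi == 0])
      expect_equal(nodes[leaf, 5], dim_est, tolerance = 1e-10)
      expect_gte(sum(wi == 1), 3)
      expect_gte(sum(wi == 0), 3)
    }
  }
})

test_that("permuting estimation-half outcomes never changes tree structure", {
  df <- forest_fixture(n = 80, seed = 7)
  fit1 <- causal_forest(df, df$w, covariates = c("x1", "x2"), n_trees = 1,
                        sample_fraction = 1, min_leaf = 2, mtry = 2,
                        centering = "none", seed = 13, keep_trees = TRUE)
  est <- fit1$trees[[1]]$est_half
  df2 <- df
  set.seed(99)
  df2$orn[est] <- df$orn[sample(est)]
  fit2 <- causal_forest(df2, df2$w, covariates = c("x1", "x2"), n_trees = 1,
                        sample_fraction = 1, min_leaf = 2, mtry = 2,
                        centering = "none", seed = 13, keep_trees = TRUE)
  n1 <- fit1$trees[[1]]$nodes
  n2 <- fit2$trees[[1]]$nodes
  expect_gt(nrow(n1), 1)                        # the tree actually split
  expect_identical(n1[, 1:4], n2[, 1:4])        # same structure
  expect_false(isTRUE(all.equal(n1[, 5], n2[, 5])))  # different leaf effects
})

test_that("OOB aggregation uses exactly the trees that excluded each sample", {
  df <- forest_fixture(n = 100, seed = 9)
  cf <- causal_forest(df, df$w, covariates = c("x1", "x2"), n_trees = 60,
                      min_leaf = 2, mtry = 2, centering = "none",
                      seed = 4, keep_trees = TRUE)
  # recompute OOB CATE in R from the stored trees
  for (i in c(1, 37, 100)) {
    preds <- c()
    for (tr in cf$trees) {
      if (i %in% tr$subsample) next
      leaf <- leaf_id_of(tr$nodes, cf$x[i, ])
      preds <- c(preds, tr$nodes[leaf, 5])
    }
    expect_equal(length(preds), cf$oob_count[i])
    expect_equal(mean(preds), cf$tau_oob[i], tolerance = 1e-12)
  }
  # subsample fraction 0.5 -> about half the trees are OOB for everyone
  expect_true(all(cf$oob_count >= 15 & cf$oob_count <= 45))
  # sampling the full cohort leaves no OOB trees at all
  cf_full <- causal_forest(df, df$w, covariates = c("x1", "x2"), n_trees = 2,
                           sample_fraction = 1, centering = "none", seed = 1)
  expect_error(oob_cate(cf_full), "no OOB tree")
})

test_that("forest fits are bit-identical under a fixed seed", {
  co <- test_cohort(n_per_arm = 150, seed = 6)
  tv <- binarize(co, "V60Gy", 40)
  f1 <- causal_forest(co, tv, n_trees = 50, centering = "parametric", seed = 5)
  f2 <- causal_forest(co, tv, n_trees = 50, centering = "parametric", seed = 5)
  expect_identical(f1$tau_oob, f2$tau_oob)
  expect_identical(estimate_ate(f1), estimate_ate(f2))
  f3 <- causal_forest(co, tv, n_trees = 50, centering = "parametric", seed = 6)
  expect_false(identical(f1$tau_oob, f3$tau_oob))
})

test_that("randomized treatment recovers the true risk difference", {
  co <- test_cohort(n_per_arm = 600, seed = 23, effect = 0.3,
                    confounding_dose = 0)
  tv <- binarize(co, "V60Gy", 40)
  cf <- causal_forest(co, tv, n_trees = 200, centering = "parametric", seed = 8)
  est <- estimate_ate(cf)
  naive <- mean(co$orn[tv == 1]) - mean(co$orn[tv == 0])
  expect_lt(abs(est$ate - 0.3), 3 * est$se)
  expect_lt(abs(est$ate - naive), 0.05)       # RCT equivalence
  expect_lt(abs(mean(oob_cate(cf)$tau) - 0.3), 0.06)
  # interval arithmetic and estimand bounds
  expect_equal(est$ci_lo, est$ate - 1.96 * est$se)
  expect_lte(abs(est$ate), 1)
  expect_equal(est$n_treated + est$n_control, nrow(co))
})

test_that("a null effect yields an ATE indistinguishable from zero", {
  co <- test_cohort(n_per_arm = 400, seed = 29, effect = 0,
                    confounding_dose = 0)
  tv <- binarize(co, "V60Gy", 40)
  est <- estimate_ate(causal_forest(co, tv, n_trees = 150,
                                    centering = "parametric", seed = 3))
  expect_lt(abs(est$ate), 3 * est$se)
})

test_that("degenerate treatments are rejected with clear errors", {
  co <- test_cohort(n_per_arm = 50, seed = 1)
  expect_error(causal_forest(co, rep(1L, nrow(co))), "degenerate arm")
  expect_error(causal_forest(co, rep(2L, nrow(co))), "binary")
})

test_that("tidy and glance summarise a fitted forest", {
  co <- test_cohort(n_per_arm = 100, seed = 2)
  cf <- causal_forest(co, binarize(co, "V60Gy", 40), n_trees = 50,
                      centering = "parametric", seed = 1)
  td <- tidy(cf)
  expect_equal(nrow(td), nrow(co))
  expect_true(all(c("tau", "y_hat", "w_hat") %in% names(td)))
  gl <- glance(cf)
  expect_equal(gl$n_trees, 50)
  expect_equal(gl$centering, "parametric")
})
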