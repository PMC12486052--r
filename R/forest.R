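#' Fit an honest causal forest
#'
#' Estimates heterogeneous effects of a binary treatment (a thresholded
#' dosimetric factor) on a binary outcome given clinical covariates. Each
#' tree is grown on a subsample drawn without replacement, split into a
#' structure half (used only to choose splits, scored by the size-weighted
#' squared difference of child treatment-effect estimates) and an estimation
#' half (used only for leaf effects) -- the honesty discipline. By default
#' the outcome and treatment are locally centered first by subtracting
#' out-of-bag regression-forest predictions of E(Y | X) and E(T | X), which
#' is what lets the forest control observed confounding; `centering = "none"`
#' disables this for ablation and for exact hand-checkable splits.
#'
#' @param data Cohort tibble.
#' @param treatment 0/1 vector (e.g. from [binarize()]) or the name of a 0/1
#'   column in `data`.
#' @param outcome Outcome column name (binary 0/1, analysed as numeric so
#'   effects are risk differences).
#' @param covariates Clinical covariate columns (default: schema attribute).
#' @param n_trees Number of trees (default 2000).
#' @param sample_fraction Subsample fraction per tree, without replacement.
#' @param honesty_fraction Share of each subsample reserved for honest leaf
#'   estimation.
#' @param min_leaf Minimum treated and minimum control estimation-half
#'   samples required in every leaf (counted separately in each arm).
#' @param mtry Covariates tried per split; default `min(ceiling(sqrt(p)) +
#'   20, p)`.
#' @param centering Nuisance models used for local centering: `"forest"`
#'   (default; OOB regression-forest predictions of E(Y | X) and E(T | X)),
#'   `"parametric"` (linear model for Y, logistic for T -- much faster, used
#'   for heavily replicated bootstrap work), or `"none"` (ablation; raw Y
#'   and T).
#' @param centering_trees Trees in each centering regression forest.
#' @param nuisance Optional list with precomputed `y_hat` and/or `w_hat`
#'   vectors (e.g. to reuse the outcome regression across a threshold scan).
#' @param seed Integer seed; identical seed, data and config give identical
#'   fits to the last bit.
#' @param keep_trees Keep per-tree structures (needed for [oob_cate()] tree
#'   introspection and honesty checks; adds memory).
#' @return Object of class `"causal_forest"`.
#' @export
causal_forest <- function(data, treatment, outcome = "orn", covariates = NULL,
                          n_trees = 2000, sample_fraction = 0.5,
                          honesty_fraction = 0.5, min_leaf = 5, mtry = NULL,
                          centering = c("forest", "parametric", "none"),
                          centering_trees = 500, nuisance = NULL, seed = 1,
                          keep_trees = FALSE) {
  centering <- match.arg(centering)
  stopifnot(sample_fraction > 0, sample_fraction <= 1,
            honesty_fraction > 0, honesty_fraction < 1, min_leaf >= 1)
  covariates <- covariates %||% attr(data, "schema")$covariates
  x <- one_hot(data, covariates)
  w <- if (is.character(treatment) && length(treatment) == 1) {
    data[[treatment]]
  } else {
    treatment
  }
  w <- as.integer(w)
  if (!all(w %in% c(0L, 1L))) stop("treatment must be binary 0/1")
  if (all(w == 1L) || all(w == 0L)) stop("degenerate arm: treatment is constant")
  y <- as.numeric(data[[outcome]])
  n <- nrow(x)
  p <- ncol(x)
  mtry <- mtry %||% min(ceiling(sqrt(p)) + 20, p)

  y_hat <- nuisance$y_hat %||% fit_nuisance(x, y, centering, centering_trees,
                                            fold_seed(seed, 1), binary = FALSE)
  w_hat <- nuisance$w_hat %||% fit_nuisance(x, w, centering, centering_trees,
                                            fold_seed(seed, 2), binary = TRUE)
  if (centering == "none") {
    yc <- y
    wc <- as.numeric(w)
  } else {
    yc <- y - y_hat
    wc <- w - w_hat
  }

  fit <- .cf_fit(x, yc, wc, w, as.integer(n_trees), sample_fraction,
                 honesty_fraction, as.integer(min_leaf), as.integer(mtry),
                 as.integer(fold_seed(seed, 3)), keep_trees)
  structure(list(tau_oob = fit$tau_oob, oob_count = fit$oob_count,
                 trees = fit$trees, x = x, y = y, w = w,
                 y_hat = y_hat, w_hat = w_hat,
                 config = list(n_trees = n_trees,
                               sample_fraction = sample_fraction,
                               honesty_fraction = honesty_fraction,
                               min_leaf = min_leaf, mtry = mtry,
                               centering = centering,
                               centering_trees = centering_trees,
                               seed = seed, covariates = covariates,
                               outcome = outcome)),
            class = "causal_forest")
}

# Nuisance predictions E(Y | X) / E(T | X) for local centering and for the
# AIPW propensity and outcome regressions.
fit_nuisance <- function(x, y, centering, num_trees, seed, binary) {
  y <- as.numeric(y)
  if (centering == "none") return(rep(mean(y), length(y)))
  if (centering == "parametric") {
    if (binary) {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y, family = binomial()))
      return(as.numeric(fit$fitted.values))
    }
    return(as.numeric(stats::lm.fit(cbind(1, x), y)$fitted.values))
  }
  rf <- ranger::ranger(y = y, x = as.data.frame(x), num.trees = num_trees,
                       seed = seed, num.threads = 1)
  pred <- rf$predictions
  pred[is.nan(pred)] <- mean(y)
  pred
}

# deterministic seed fan-out (kept below 2^31)
fold_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1009 * as.numeric(k)) %% 2147483647
}

#' Out-of-bag CATE predictions
#'
#' Per-sample conditional average treatment effect, averaged over only the
#' trees whose subsample excluded that sample, so the whole cohort is scored
#' without a train/test split.
#'
#' @param model A `"causal_forest"`.
#' @return Tibble with columns `tau`, `n_oob_trees`.
#' @export
oob_cate <- function(model) {
  stopifnot(inherits(model, "causal_forest"))
  if (any(model$oob_count == 0)) {
    stop("some samples appear in every subsample and have no OOB tree; ",
         "use sample_fraction < 1")
  }
  tibble::tibble(tau = model$tau_oob, n_oob_trees = model$oob_count)
}

#' @export
predict.causal_forest <- function(object, ...) oob_cate(object)

#' Average treatment effect from a fitted causal forest
#'
#' Default estimator is the doubly-robust AIPW score: each patient
#' contributes `tau(x) + (T - e(x)) / (e(x)(1 - e(x))) * (Y - m(x) -
#' (T - e(x)) tau(x))` with `tau(x)` the OOB CATE, `e(x)` the
#' forest-estimated treatment propensity and `m(x)` the outcome regression;
#' the ATE is the mean score and its standard error the score SD over
#' sqrt(n). `method = "mean"` returns the plain mean of OOB CATEs as a
#' cross-check. With the binary outcome the ATE is a risk difference in
#' [-1, 1]. If the estimated propensity leaves [0.01, 0.99] for more than 5%
#' of patients a positivity warning is attached.
#'
#' @param model A `"causal_forest"`.
#' @param method `"aipw"` (default) or `"mean"`.
#' @return One-row tibble of class `"ate_estimate"`: `ate`, `se`, `ci_lo`,
#'   `ci_hi`, `n_treated`, `n_control`, `method`.
#' @export
estimate_ate <- function(model, method = c("aipw", "mean")) {
  stopifnot(inherits(model, "causal_forest"))
  method <- match.arg(method)
  tau <- model$tau_oob
  if (any(model$oob_count == 0)) stop("OOB CATE unavailable for some samples")
  n <- length(tau)
  eps <- 0.01
  if (method == "aipw") {
    e <- pmin(pmax(model$w_hat, eps), 1 - eps)
    m <- model$y_hat
    mu0 <- m - e * tau
    mu1 <- mu0 + tau
    w <- model$w
    y <- model$y
    score <- tau + w / e * (y - mu1) - (1 - w) / (1 - e) * (y - mu0)
  } else {
    score <- tau
  }
  ate <- mean(score)
  se <- sd(score) / sqrt(n)
  out <- tibble::tibble(ate = ate, se = se,
                        ci_lo = ate - 1.96 * se, ci_hi = ate + 1.96 * se,
                        n_treated = sum(model$w == 1),
                        n_control = sum(model$w == 0),
                        method = method)
  viol <- mean(model$w_hat < eps | model$w_hat > 1 - eps)
  if (viol > 0.05) {
    attr(out, "positivity_warning") <-
      sprintf("estimated propensity outside [%.2f, %.2f] for %.1f%% of samples",
              eps, 1 - eps, 100 * viol)
    warning(attr(out, "positivity_warning"))
  }
  class(out) <- c("ate_estimate", class(out))
  out
}

#' @export
tidy.causal_forest <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample = seq_along(x$tau_oob)), oob_cate(x),
                   tibble::tibble(y_hat = x$y_hat, w_hat = x$w_hat))
}

#' @export
glance.causal_forest <- function(x, ...) {
  est <- suppressWarnings(estimate_ate(x))
  tibble::tibble(n = length(x$y), n_trees = x$config$n_trees,
                 ate = est$ate, se = est$se,
                 mean_oob_trees = mean(x$oob_count),
                 centering = x$config$centering)
}

#' @export
print.causal_forest <- function(x, ...) {
  cat("Honest causal forest:", x$config$n_trees, "trees,",
      length(x$y), "samples,", ncol(x$x), "features, centering:",
      x$config$centering, "\n")
  invisible(x)
}
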