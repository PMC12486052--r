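#' Estimate propensity scores for modality assignment
#'
#' Fits a maximum-likelihood logistic regression of P(modality = PBSPT |
#' clinical covariates) on the one-hot-encoded covariates (age linear,
#' categorical levels as indicators including `MISSING`). Perfect separation
#' by a single covariate is reported as an error naming that covariate;
#' near-separation (fitted probabilities collapsing to 0/1) falls back to a
#' lightly ridge-penalized fit (lambda = 1e-6) so that scores remain inside
#' (0, 1) and reproducible.
#'
#' @param data Cohort tibble.
#' @param covariates Clinical covariate columns (default: schema attribute).
#' @param modality,treated_level Modality column and the level coded 1.
#' @return Tibble with columns `patient_id` (if present), `modality`,
#'   `propensity`.
#' @export
estimate_propensity <- function(data, covariates = NULL, modality = "modality",
                                treated_level = "PBSPT") {
  covariates <- covariates %||% attr(data, "schema")$covariates
  x <- one_hot(data, covariates)
  z <- as.numeric(data[[modality]] == treated_level)
  if (all(z == 1) || all(z == 0)) stop("both modality groups must be present")
  # a single indicator that perfectly predicts modality => separation
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (all(v %in% c(0, 1)) && length(unique(v)) == 2) {
      if (all(z[v == 1] == 1) && all(z[v == 0] == 0) ||
          all(z[v == 1] == 0) && all(z[v == 0] == 1)) {
        stop("complete separation: covariate column '", colnames(x)[j],
             "' perfectly predicts modality")
      }
    }
  }
  fit <- suppressWarnings(glm(z ~ x, family = binomial()))
  p <- fit$fitted.values
  eps <- 1e-8
  if (!fit$converged || any(p < eps) || any(p > 1 - eps)) {
    # near-separation: ridge fallback keeps scores strictly inside (0, 1)
    rf <- glmnet::glmnet(x, z, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    p <- as.numeric(predict(rf, newx = x, type = "response"))
  }
  out <- tibble::tibble(modality = data[[modality]], propensity = as.numeric(p))
  if ("patient_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = data$patient_id), out)
  }
  out
}

# Exact 1:1 optimal matching of two groups on a scalar distance.
# For L1 distances on a scalar score the optimal assignment is order
# preserving (no two matched pairs "cross"), so the global optimum over all
# 1:1 assignments is found by dynamic programming on the two sorted score
# vectors: f[i, j] = cost of matching the first i of the smaller group within
# the first j of the larger group. O(n * m), provably optimal.
match_scalar_optimal <- function(s_small, s_large) {
  m <- length(s_small); M <- length(s_large)
  os <- order(s_small); ol <- order(s_large)
  a <- s_small[os]; b <- s_large[ol]
  f <- matrix(Inf, m + 1, M + 1)
  f[1, ] <- 0
  for (i in seq_len(m)) {
    for (j in i:M) {
      take <- f[i, j] + abs(a[i] - b[j])
      skip <- if (j > i) f[i + 1, j] else Inf
      f[i + 1, j + 1] <- min(take, skip)
    }
  }
  # backtrack
  pairs <- integer(m)
  j <- M
  for (i in m:1) {
    while (j > i && f[i + 1, j + 1] == f[i + 1, j]) j <- j - 1
    pairs[i] <- j
    j <- j - 1
  }
  list(small_idx = os, large_idx = ol[pairs], total = f[m + 1, M + 1])
}

#' Optimal 1:1 propensity-score matching
#'
#' Pairs every patient of the smaller modality group with a distinct patient
#' of the larger group so that the total absolute difference in (by default
#' logit-) propensity over all pairs is globally minimal -- the optimal (not
#' greedy nearest-neighbour) matching strategy. Each patient is used at most
#' once and no caliper is applied, so the number of pairs equals the smaller
#' group size. Ties are broken by input order for determinism.
#'
#' @param scores Numeric propensity scores in (0, 1), one per patient.
#' @param group Modality label per patient (two levels).
#' @param ids Optional patient ids (default: positions).
#' @param distance `"logit"` (default; distances on log-odds of the score,
#'   common PSM practice) or `"raw"`.
#' @return Tibble of pairs with columns `id_1`, `id_2`, `score_1`, `score_2`,
#'   `distance`, where group 1 is the first level encountered; attribute
#'   `total_distance` holds the minimized objective on the chosen scale.
#' @export
match_optimal <- function(scores, group, ids = NULL,
                          distance = c("logit", "raw")) {
  distance <- match.arg(distance)
  ids <- ids %||% as.character(seq_along(scores))
  lev <- unique(group)
  if (length(lev) != 2) stop("need exactly two non-empty groups; found ", length(lev))
  g1 <- which(group == lev[1]); g2 <- which(group == lev[2])
  if (!length(g1) || !length(g2)) stop("empty modality group")
  s <- if (distance == "logit") qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12)) else scores
  if (length(g1) <= length(g2)) { small <- g1; large <- g2 } else { small <- g2; large <- g1 }
  res <- match_scalar_optimal(s[small], s[large])
  i_small <- small[res$small_idx]; i_large <- large[res$large_idx]
  # report with group lev[1] first regardless of which side was smaller
  if (identical(small, g1)) { i1 <- i_small; i2 <- i_large } else { i1 <- i_large; i2 <- i_small }
  out <- tibble::tibble(id_1 = ids[i1], id_2 = ids[i2],
                        score_1 = scores[i1], score_2 = scores[i2],
                        distance = abs(s[i1] - s[i2]))
  out <- dplyr::arrange(out, .data$id_1)
  attr(out, "total_distance") <- res$total
  attr(out, "groups") <- setNames(as.character(lev), c("id_1", "id_2"))
  out
}

#' Between-group balance tests
#'
#' Compares the two modality groups covariate by covariate: chi-square test
#' (without continuity correction) on the level-by-modality contingency table
#' for categorical factors, and a two-sided two-sample t-test for continuous
#' factors such as age. A covariate with a single observed level is reported
#' with p = 1 and a warning. The conventional 0.05 threshold is reported, not
#' enforced.
#'
#' @param data Cohort tibble.
#' @param covariates Covariate columns (default: schema attribute).
#' @param modality Modality column.
#' @param subset Optional logical/integer row subset (e.g. matched patients).
#' @return Tibble with columns `covariate`, `type`, `statistic`, `p_value`.
#' @export
balance_tests <- function(data, covariates = NULL, modality = "modality",
                          subset = NULL) {
  covariates <- covariates %||% attr(data, "schema")$covariates
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  g <- data[[modality]]
  if (length(unique(g)) != 2) stop("need two modality groups in the (subset of the) cohort")
  purrr::map_dfr(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x)) {
      if (sd(x) == 0) {
        warning("covariate '", cv, "' is constant; p = 1")
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- t.test(x ~ g)
      }
      tibble::tibble(covariate = cv, type = "continuous",
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      x <- as.character(x)
      if (length(unique(x)) < 2) {
        warning("covariate '", cv, "' has a single level; p = 1")
        return(tibble::tibble(covariate = cv, type = "categorical",
                              statistic = 0, p_value = 1))
      }
      ct <- suppressWarnings(chisq.test(table(x, g), correct = FALSE))
      tibble::tibble(covariate = cv, type = "categorical",
                     statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  })
}

#' Propensity-match two modality cohorts end to end
#'
#' Estimates propensity scores, finds the optimal 1:1 pairing, and evaluates
#' covariate balance before and after matching.
#'
#' @inheritParams estimate_propensity
#' @param distance Matching distance scale, see [match_optimal()].
#' @return Object of class `"matched_cohort"`: list with `pairs`,
#'   `propensity`, `balance_before`, `balance_after`, `matched_ids`, and the
#'   matched cohort tibble `matched`.
#' @export
match_cohorts <- function(data, covariates = NULL, modality = "modality",
                          treated_level = "PBSPT", distance = "logit") {
  covariates <- covariates %||% attr(data, "schema")$covariates
  ids <- if ("patient_id" %in% names(data)) data$patient_id else as.character(seq_len(nrow(data)))
  ps <- estimate_propensity(data, covariates, modality, treated_level)
  pairs <- match_optimal(ps$propensity, data[[modality]], ids = ids,
                         distance = distance)
  matched_ids <- c(pairs$id_1, pairs$id_2)
  keep <- ids %in% matched_ids
  matched <- data[keep, , drop = FALSE]
  attr(matched, "schema") <- attr(data, "schema")  # subsetting drops attrs
  structure(list(pairs = pairs,
                 propensity = ps,
                 balance_before = balance_tests(data, covariates, modality),
                 balance_after = balance_tests(data, covariates, modality,
                                               subset = keep),
                 matched_ids = matched_ids,
                 matched = matched),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort:", nrow(x$pairs), "pairs;",
      "total propensity distance", format(attr(x$pairs, "total_distance"), digits = 4), "\n")
  invisible(x)
}

#' Balance report in before/after layout
#'
#' @param x A `"matched_cohort"`.
#' @param ... Unused.
#' @return Tibble with `covariate`, `p_before`, `p_after`.
#' @export
tidy.matched_cohort <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(x$balance_before, "covariate", p_before = "p_value"),
    dplyr::select(x$balance_after, "covariate", p_after = "p_value"),
    by = "covariate")
}

#' @export
glance.matched_cohort <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 total_distance = attr(x$pairs, "total_distance"),
                 n_imbalanced_before = sum(x$balance_before$p_value < 0.05),
                 n_imbalanced_after = sum(x$balance_after$p_value < 0.05))
}
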