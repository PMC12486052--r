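#' Pairwise standardized mean difference
#'
#' SMD between two samples: |mean_i - mean_j| / sqrt((var_i + var_j) / 2),
#' the magnitude of the mean difference in units of the pooled standard
#' deviation. When both samples are constant and equal the SMD is 0; when the
#' pooled SD is 0 but the means differ the SMD is reported as `Inf` (a
#' degenerate, perfectly separated comparison), never as an error.
#'
#' @param x,y Numeric samples (for a categorical factor, the per-level 0/1
#'   indicator values).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
#' @examples
#' pairwise_smd(rnorm(50, 1), rnorm(50, 0))
pairwise_smd <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  s2 <- (stats::var(x) %|0|% 0 + stats::var(y) %|0|% 0) / 2
  d <- abs(mean(x) - mean(y))
  if (s2 == 0) {
    if (d == 0) 0 else Inf
  } else {
    d / sqrt(s2)
  }
}

# var() of a length-1 sample is NA; treat it as zero spread
`%|0|%` <- function(a, b) if (is.na(a)) b else a

# Quartile strata of a dosimetric factor: low / mid-low / mid-high / high.
# Sample quartiles as right-closed cut points, so ties at a cut point fall in
# the lower stratum (deterministic under heavily tied volumes, e.g. V70 = 0).
dose_strata <- function(v) {
  qs <- unique(quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7))
  strata <- findInterval(v, qs, left.open = TRUE) + 1L
  if (length(unique(strata)) < 2) {
    stop("dosimetric factor is (nearly) constant; cannot stratify into quartiles")
  }
  strata
}

#' Worst-case SMD of a clinical factor across dose quartile strata
#'
#' Stratifies the cohort into four subgroups (high / mid-high / mid-low /
#' low) by sample quartiles of a dosimetric factor and returns the maximum
#' pairwise SMD of the clinical factor over all stratum pairs. For a
#' categorical clinical factor the SMD is computed on per-level indicators
#' and the maximum is also taken over levels (worst case throughout).
#'
#' @param data Cohort tibble.
#' @param clinical Clinical factor column.
#' @param dosimetric Dosimetric factor column.
#' @return Scalar `SMD_max` (possibly `Inf` for a degenerate comparison).
#' @export
smd_max <- function(data, clinical, dosimetric) {
  if (nrow(data) < 8) stop("need at least 8 records (2 per quartile stratum)")
  strata <- dose_strata(data[[dosimetric]])
  x <- data[[clinical]]
  columns <- if (is.numeric(x)) {
    list(as.numeric(x))
  } else {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- MISSING_LEVEL
    lapply(sort(unique(x)), function(l) as.numeric(x == l))
  }
  ids <- sort(unique(strata))
  prs <- utils::combn(ids, 2)
  max(purrr::map_dbl(columns, function(col) {
    max(apply(prs, 2, function(pr) {
      pairwise_smd(col[strata == pr[1]], col[strata == pr[2]])
    }))
  }))
}

#' Within-group SMD report over all clinical x dosimetric pairs
#'
#' For one modality group, computes `SMD_max` of every clinical factor
#' conditional on every dosimetric factor and flags each cell:
#' `balanced` (< 0.2), `moderate` (0.2 to < 0.8), `high` (>= 0.8), or
#' `degenerate` (infinite SMD from a zero-variance, unequal-mean pair).
#' Classification intervals are closed on the left.
#'
#' @param data Cohort tibble.
#' @param group Modality level to report on, or `NULL` for all rows.
#' @param clinical,dosimetric Factor columns (default: schema attribute).
#' @param modality Modality column.
#' @return Tibble of class `"smd_matrix"` with columns `clinical`,
#'   `dosimetric`, `smd_max`, `flag`.
#' @export
smd_report <- function(data, group = NULL, clinical = NULL, dosimetric = NULL,
                       modality = "modality") {
  sch <- attr(data, "schema")
  clinical <- clinical %||% sch$covariates
  dosimetric <- dosimetric %||% sch$dosimetric
  if (!is.null(group)) {
    data <- data[data[[modality]] == group, , drop = FALSE]
    if (!nrow(data)) stop("modality group '", group, "' is empty")
  }
  grid <- tidyr::expand_grid(clinical = clinical, dosimetric = dosimetric)
  out <- dplyr::mutate(grid,
    smd_max = purrr::map2_dbl(clinical, dosimetric,
                              function(cl, dv) smd_max(data, cl, dv)),
    flag = smd_flag(.data$smd_max))
  class(out) <- c("smd_matrix", class(out))
  attr(out, "group") <- group
  out
}

smd_flag <- function(s) {
  dplyr::case_when(is.infinite(s) ~ "degenerate",
                   s >= 0.8 ~ "high",
                   s >= 0.2 ~ "moderate",
                   TRUE ~ "balanced")
}

#' Heatmap of a within-group SMD report
#'
#' Three-band coloring: balanced (< 0.2), moderately biased (0.2 to < 0.8,
#' yellow), highly biased (>= 0.8, orange).
#'
#' @param object An `"smd_matrix"` from [smd_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smd_matrix <- function(object, ...) {
  lv <- c("balanced", "moderate", "high", "degenerate")
  df <- dplyr::mutate(tibble::as_tibble(object), flag = factor(.data$flag, lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dosimetric, y = .data$clinical,
                                   fill = .data$flag)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.finite(df$smd_max), sprintf("%.2f", df$smd_max), "deg.")),
      size = 3) +
    ggplot2::scale_fill_manual(
      values = c(balanced = "grey90", moderate = "gold",
                 high = "darkorange", degenerate = "firebrick"),
      drop = FALSE) +
    ggplot2::labs(x = "dosimetric factor", y = "clinical factor",
                  fill = "worst-case SMD",
                  title = if (is.null(attr(object, "group"))) NULL
                          else paste("Within-group balance:", attr(object, "group")))
}
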