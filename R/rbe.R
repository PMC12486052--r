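#' Build a volume tolerance curve
#'
#' Orders derived (dose level, critical volume) pairs into one modality's
#' tolerance curve. Dose levels must be distinct; a curve whose critical
#' volume is not non-increasing in dose is physically surprising and is
#' flagged with a warning but kept as given.
#'
#' @param dose_level Dose levels in Gy on the modality's reported scale
#'   (physical Gy for photons, Gy`[`RBE=1.1`]` for protons).
#' @param critical_volume Critical volumes in cc at each dose level.
#' @param modality Label, e.g. `"VMAT"` or `"PBSPT"`.
#' @param dose_scale `"photon_physical"` or `"proton_rbe11"`.
#' @param ci_lo,ci_hi Optional per-point 95% CI bounds for plotting.
#' @return Tibble of class `"tolerance_curve"`, sorted by dose.
#' @export
#' @examples
#' tolerance_curve(c(40, 50, 60, 70), c(82.92, 76.25, 57.77, 7.05), "VMAT")
tolerance_curve <- function(dose_level, critical_volume, modality = "VMAT",
                            dose_scale = if (modality == "VMAT")
                              "photon_physical" else "proton_rbe11",
                            ci_lo = NULL, ci_hi = NULL) {
  if (length(dose_level) < 2) stop("a tolerance curve needs at least 2 dose levels")
  if (anyDuplicated(dose_level)) stop("duplicate dose levels in tolerance curve")
  o <- order(dose_level)
  out <- tibble::tibble(dose_level = dose_level[o],
                        critical_volume = critical_volume[o],
                        modality = modality)
  if (!is.null(ci_lo)) out$ci_lo <- ci_lo[o]
  if (!is.null(ci_hi)) out$ci_hi <- ci_hi[o]
  if (any(diff(out$critical_volume) > 1e-9)) {
    warning("critical volume is not non-increasing in dose for ", modality,
            " tolerance curve")
  }
  class(out) <- c("tolerance_curve", class(out))
  attr(out, "dose_scale") <- dose_scale
  out
}

#' Volume attained by a tolerance curve at a dose
#'
#' Piecewise-linear interpolation of the curve in (dose, volume) space;
#' queries outside the knot range are an error (no extrapolation).
#'
#' @param curve A `"tolerance_curve"`.
#' @param dose Dose on the curve's scale.
#' @return Volume in cc.
#' @export
volume_at <- function(curve, dose) {
  rng <- range(curve$dose_level)
  if (any(dose < rng[1] - 1e-12 | dose > rng[2] + 1e-12)) {
    stop("dose outside tolerance-curve range [", rng[1], ", ", rng[2], "]")
  }
  approx(curve$dose_level, curve$critical_volume, xout = dose,
         ties = "ordered")$y
}

#' Equivalent constraint dose on a photon tolerance curve
#'
#' Inverts the (piecewise-linear) photon tolerance curve: the photon dose at
#' which the interpolated curve attains `target_volume`, i.e. the dose whose
#' photon critical volume equals a proton critical volume. If a non-monotone
#' curve attains the target on several segments the lowest such dose is
#' returned with a warning. Targets outside the curve's volume range are an
#' extrapolation error.
#'
#' @param photon_curve A `"tolerance_curve"` on the photon physical scale.
#' @param target_volume Target critical volume in cc.
#' @return Equivalent dose in Gy`[`RBE=1.0`]`.
#' @export
#' @examples
#' cv <- tolerance_curve(c(60, 70), c(57.77, 7.05), "VMAT")
#' equivalent_dose(cv, 32.41)  # midpoint of the segment -> 65 Gy
equivalent_dose <- function(photon_curve, target_volume) {
  d <- photon_curve$dose_level
  v <- photon_curve$critical_volume
  if (target_volume > max(v) + 1e-12 || target_volume < min(v) - 1e-12) {
    stop("target volume ", target_volume, " cc outside the photon curve's ",
         "volume range [", min(v), ", ", max(v), "]; refusing to extrapolate")
  }
  hits <- numeric(0)
  for (k in seq_len(length(d) - 1)) {
    v1 <- v[k]; v2 <- v[k + 1]
    lo <- min(v1, v2); hi <- max(v1, v2)
    if (target_volume >= lo - 1e-12 && target_volume <= hi + 1e-12) {
      hit <- if (v1 == v2) d[k]
             else d[k] + (target_volume - v1) / (v2 - v1) * (d[k + 1] - d[k])
      hits <- c(hits, hit)
    }
  }
  hits <- sort(unique(round(hits, 12)))
  if (!length(hits)) stop("target volume not attained on any curve segment")
  if (length(hits) > 1) {
    warning("target volume attained on multiple segments; returning the ",
            "lowest equivalent dose")
  }
  hits[1]
}

#' Empirical proton RBE from an equivalent constraint dose
#'
#' Proton plans prescribe in Gy`[`RBE=1.1`]`, i.e. physical dose times 1.1.
#' The empirical RBE at a nominal proton dose is the equivalent photon
#' constraint dose divided by the proton physical dose:
#' `RBE = equiv_dose / (nominal_proton_dose / 1.1)`.
#'
#' @param equiv_dose Equivalent photon dose, Gy`[`RBE=1.0`]`.
#' @param nominal_proton_dose Nominal proton dose, Gy`[`RBE=1.1`]`.
#' @return RBE (dimensionless, > 0).
#' @export
#' @examples
#' empirical_rbe(58.58, 40)  # 1.611
empirical_rbe <- function(equiv_dose, nominal_proton_dose) {
  if (any(equiv_dose <= 0) || any(nominal_proton_dose <= 0)) {
    stop("doses must be positive")
  }
  equiv_dose / (nominal_proton_dose / 1.1)
}

#' Point-estimate RBE table from paired tolerance curves
#'
#' For each requested nominal proton dose: read the proton critical volume
#' off the proton curve, find the photon dose with the same critical volume
#' on the photon curve (equivalent constraint dose), and form the RBE as its
#' ratio to the proton physical dose.
#'
#' @param photon_curve,proton_curve `"tolerance_curve"` objects.
#' @param nominal_doses Nominal proton dose levels, Gy`[`RBE=1.1`]`.
#' @return Tibble with columns `nominal_proton_dose`, `proton_physical_dose`,
#'   `proton_volume`, `equivalent_dose`, `rbe`.
#' @export
rbe_table <- function(photon_curve, proton_curve, nominal_doses) {
  purrr::map_dfr(nominal_doses, function(d) {
    pv <- volume_at(proton_curve, d)
    ed <- equivalent_dose(photon_curve, pv)
    tibble::tibble(nominal_proton_dose = d,
                   proton_physical_dose = d / 1.1,
                   proton_volume = pv,
                   equivalent_dose = ed,
                   rbe = empirical_rbe(ed, d))
  })
}

#' RBE table with bootstrap confidence intervals
#'
#' Combines paired bootstrap replicates of the photon and proton tolerance
#' curves: per replicate the equivalent dose and RBE are recomputed at each
#' nominal dose, and percentile 95% intervals are formed. Replicates whose
#' proton volume falls outside the photon curve's volume range (an
#' extrapolation) are dropped and counted; if more than 20% are dropped at a
#' dose level the interval is flagged unreliable.
#'
#' @param photon_boot,proton_boot Lists of `"tolerance_curve"` replicates
#'   (equal length, paired by index).
#' @param nominal_doses Nominal proton dose levels, Gy`[`RBE=1.1`]`.
#' @param point Optional point-estimate [rbe_table()] rows to carry through;
#'   defaults to replicate medians only.
#' @return Tibble of class `"rbe_table"`: per dose level the point RBE (if
#'   given), `rbe_lo`, `rbe_hi`, `equiv_lo`, `equiv_hi`, `n_used`,
#'   `n_dropped`, `unreliable`.
#' @export
rbe_with_ci <- function(photon_boot, proton_boot, nominal_doses, point = NULL) {
  stopifnot(length(photon_boot) == length(proton_boot),
            length(photon_boot) >= 1)
  purrr::map_dfr(nominal_doses, function(d) {
    draws <- purrr::map2(photon_boot, proton_boot, function(ph, pr) {
      tryCatch({
        pv <- volume_at(pr, d)
        ed <- suppressWarnings(equivalent_dose(ph, pv))
        c(ed = ed, rbe = empirical_rbe(ed, d))
      }, error = function(e) c(ed = NA_real_, rbe = NA_real_))
    })
    ed <- purrr::map_dbl(draws, "ed")
    rbe <- purrr::map_dbl(draws, "rbe")
    used <- sum(!is.na(rbe))
    dropped <- sum(is.na(rbe))
    qs <- function(x) quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci_r <- qs(rbe); ci_e <- qs(ed)
    row <- tibble::tibble(nominal_proton_dose = d,
                          proton_physical_dose = d / 1.1,
                          rbe = if (!is.null(point))
                            point$rbe[point$nominal_proton_dose == d]
                          else median(rbe, na.rm = TRUE),
                          rbe_lo = ci_r[1], rbe_hi = ci_r[2],
                          equiv_lo = ci_e[1], equiv_hi = ci_e[2],
                          n_used = used, n_dropped = dropped,
                          unreliable = dropped > 0.2 * (used + dropped))
    if (row$unreliable) {
      warning("more than 20% of bootstrap replicates extrapolated at ",
              d, " Gy; CI flagged unreliable")
    }
    row
  })
}

#' Plot paired volume tolerance curves
#'
#' Photon and proton tolerance curves with optional 95% CI error bars and
#' the equivalent-constraint-dose construction (horizontal line at each
#' proton critical volume to its intersection with the photon curve).
#'
#' @param photon_curve,proton_curve `"tolerance_curve"` objects.
#' @param nominal_doses Proton dose levels at which to draw the construction
#'   lines (omit with `NULL`).
#' @return A ggplot object.
#' @export
plot_tolerance_curves <- function(photon_curve, proton_curve,
                                  nominal_doses = NULL) {
  df <- dplyr::bind_rows(tibble::as_tibble(photon_curve),
                         tibble::as_tibble(proton_curve))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_level,
                                        y = .data$critical_volume,
                                        color = .data$modality)) +
    ggplot2::geom_line() + ggplot2::geom_point()
  if (all(c("ci_lo", "ci_hi") %in% names(df))) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                                 ymax = .data$ci_hi),
                                    width = 0.8)
  }
  if (!is.null(nominal_doses)) {
    seg <- purrr::map_dfr(nominal_doses, function(d) {
      pv <- volume_at(proton_curve, d)
      tibble::tibble(x = d, xend = equivalent_dose(photon_curve, pv),
                     y = pv)
    })
    p <- p + ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y),
      inherit.aes = FALSE, linetype = 3, color = "grey40",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  }
  p + ggplot2::labs(x = "dose level (Gy, modality scale)",
                    y = "critical volume (cc)")
}

#' @export
autoplot.tolerance_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$dose_level,
                               y = .data$critical_volume)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dose level (Gy)", y = "critical volume (cc)",
                  title = unique(object$modality))
}
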