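# Shared fixtures, all generated in code.

# small hand-written cohort for I/O and schema tests
mini_cohort_df <- function() {
  tibble::tibble(
    patient_id = c("A1", "A2", "B1", "B2"),
    modality = c("VMAT", "VMAT", "PBSPT", "PBSPT"),
    age = c(61, 55, 70, 64),
    tumor_stage = c("IV", "II", "I", "X"),
    gender = c("male", "female", "male", "male"),
    chemo = c("yes", "no", "yes", "yes"),
    smoking_history = c("yes", "no", "no", "yes"),
    current_smoker = c("no", "no", "no", "yes"),
    hypertension = c("yes", "no", "yes", "no"),
    diabetes = c("no", "", "yes", "no"),   # one empty cell -> MISSING
    dental_extraction = c("no", "no", "yes", "no"),
    V40Gy = c(80, 70, 35, 30),
    V50Gy = c(70, 60, 30, 25),
    V60Gy = c(50, 40, 15, 12),
    V70Gy = c(10, 5, 4, 2),
    Dmax = c(7100, 7000, 6700, 6500),
    Dmean = c(5800, 5500, 3400, 3200),
    orn = c(1, 0, 0, 0))
}

# moderately sized simulated cohort with boosted prevalence for power
test_cohort <- function(n_per_arm = 300, seed = 42, effect = 0.25,
                        base_rate = 0.1, confounding_dose = 1,
                        threshold = 40, link = "identity") {
  cfg <- sim_config(
    n_per_modality = n_per_arm,
    confounding_dose = confounding_dose,
    outcome_model = list(link = link, base_rate = base_rate, effect = effect,
                         factor = "V60Gy", threshold = threshold,
                         beta = c(dental_extraction = 0.1, current_smoker = 0.08,
                                  stage_iv = 0.08, diabetes = 0.05)))
  simulate_cohort(cfg, seed = seed)
}

# all permutations of a vector (for brute-force assignment oracles)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# exhaustive minimum total |a - b| over all 1:1 assignments of the smaller
# group into the larger one (subset choice included)
brute_force_match_total <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  m <- length(a)
  best <- Inf
  subsets <- utils::combn(seq_along(b), m, simplify = FALSE)
  for (sub in subsets) {
    for (pp in perms(sub)) {
      best <- min(best, sum(abs(a - b[pp])))
    }
  }
  best
}
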