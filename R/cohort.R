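#' @useDynLib dvcforest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
#' @importFrom stats quantile sd var median rnorm runif rbinom chisq.test t.test
#'   plogis qlogis approx coef glm binomial predict setNames
#' @importFrom utils head tail
"_PACKAGE"

#' Default cohort schema
#'
#' Column-role schema used throughout the package: which columns hold the
#' treatment modality, the binary osteoradionecrosis (ORN) outcome, the
#' clinical covariates, and the mandible dosimetric factors.
#'
#' @param modality,outcome Column names for the modality label
#'   (`"VMAT"`/`"PBSPT"`) and the 0/1 ORN outcome.
#' @param covariates Character vector of clinical covariate columns. `age` is
#'   treated as continuous; all other covariates are categorical and may
#'   contain the explicit level `"MISSING"`.
#' @param dosimetric Character vector of dosimetric factor columns. VxGy
#'   columns are absolute volumes in cc; `Dmax`/`Dmean` are doses in cGy.
#' @return A named list with class `"cohort_schema"`.
#' @export
#' @examples
#' cohort_schema()
cohort_schema <- function(modality = "modality",
                          outcome = "orn",
                          covariates = c("age", "tumor_stage", "gender", "chemo",
                                         "smoking_history", "current_smoker",
                                         "hypertension", "diabetes",
                                         "dental_extraction"),
                          dosimetric = c("V40Gy", "V50Gy", "V60Gy", "V70Gy",
                                         "Dmax", "Dmean")) {
  structure(list(modality = modality, outcome = outcome,
                 covariates = covariates, dosimetric = dosimetric),
            class = "cohort_schema")
}

#' Read a schema from a YAML file
#'
#' The YAML file maps role names (`modality`, `outcome`, `covariates`,
#' `dosimetric`) to column names.
#'
#' @param path Path to a YAML file.
#' @return A `"cohort_schema"` list.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("modality", "outcome", "covariates", "dosimetric")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("schema file lacks role(s): ", paste(missing, collapse = ", "))
  }
  cohort_schema(modality = raw$modality, outcome = raw$outcome,
                covariates = unlist(raw$covariates),
                dosimetric = unlist(raw$dosimetric))
}

# Level used for empty / NA categorical cells. Missingness is informative
# (structural, e.g. registry fields collected at one site only) and is never
# imputed; it enters every model as its own category.
MISSING_LEVEL <- "MISSING"

#' Validate a cohort table against a schema
#'
#' Checks the invariants every downstream stage relies on: a binary 0/1
#' outcome, non-negative dosimetric values, cumulative-DVH monotonicity
#' (V40Gy >= V50Gy >= V60Gy >= V70Gy per patient), Dmax >= Dmean, unique
#' patient ids, and no NA in continuous columns.
#'
#' @param data A data frame of patient records.
#' @param schema A [cohort_schema()].
#' @return `data` invisibly (as a tibble), with empty categorical cells
#'   recoded to `"MISSING"`.
#' @export
validate_cohort <- function(data, schema = cohort_schema()) {
  data <- tibble::as_tibble(data)
  needed <- c(schema$modality, schema$outcome, schema$covariates, schema$dosimetric)
  absent <- setdiff(needed, names(data))
  if (length(absent)) {
    stop("cohort is missing mandatory column(s): ", paste(absent, collapse = ", "))
  }
  if ("patient_id" %in% names(data) && anyDuplicated(data$patient_id)) {
    stop("duplicate patient_id values in cohort")
  }
  y <- data[[schema$outcome]]
  if (!all(y %in% c(0, 1))) {
    stop("outcome column '", schema$outcome, "' must be binary 0/1; found value(s): ",
         paste(unique(y[!y %in% c(0, 1)]), collapse = ", "))
  }
  for (f in schema$dosimetric) {
    v <- data[[f]]
    if (!is.numeric(v) || anyNA(v)) stop("dosimetric factor '", f, "' must be numeric without NA")
    if (any(v < 0)) stop("dosimetric factor '", f, "' contains negative values")
  }
  vx <- grep("^V[0-9]+Gy$", schema$dosimetric, value = TRUE)
  if (length(vx) > 1) {
    lev <- as.numeric(sub("^V([0-9]+)Gy$", "\\1", vx))
    vx <- vx[order(lev)]
    vol <- as.matrix(data[vx])
    if (any(vol[, -1, drop = FALSE] > vol[, -ncol(vol), drop = FALSE] + 1e-9)) {
      stop("VxGy volumes must be non-increasing in dose level for every patient")
    }
  }
  if (all(c("Dmax", "Dmean") %in% schema$dosimetric) &&
      any(data$Dmax < data$Dmean - 1e-9)) {
    stop("Dmax must be >= Dmean for every patient")
  }
  for (cv in setdiff(schema$covariates, "age")) {
    x <- as.character(data[[cv]])
    x[is.na(x) | x == ""] <- MISSING_LEVEL
    data[[cv]] <- x
  }
  if ("age" %in% schema$covariates && anyNA(data[["age"]])) {
    stop("continuous covariate 'age' may not contain NA")
  }
  attr(data, "schema") <- schema
  invisible(data)
}

#' Read a patient cohort from a delimited text file
#'
#' Empty cells in categorical covariates are coded as the explicit level
#' `"MISSING"` (never imputed) so that structurally missing registry fields
#' enter the matching and forest models as valid categories.
#'
#' @param path CSV (or TSV, by extension) file with a header row.
#' @param schema A [cohort_schema()] or path to a YAML schema file.
#' @param dose_unit Unit of `Dmax`/`Dmean` columns in the file: `"cGy"`
#'   (stored as-is, the internal unit) or `"Gy"` (converted to cGy on read).
#' @return A validated cohort tibble with the schema attached as an attribute.
#' @export
read_cohort <- function(path, schema = cohort_schema(), dose_unit = c("cGy", "Gy")) {
  dose_unit <- match.arg(dose_unit)
  if (is.character(schema)) schema <- read_schema(schema)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (dose_unit == "Gy") {
    for (f in intersect(c("Dmax", "Dmean"), schema$dosimetric)) {
      data[[f]] <- data[[f]] * 100
    }
  }
  validate_cohort(data, schema)
}

#' Write a cohort to CSV
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Extract a cumulative-DVH index VxGy
#'
#' Given a cumulative dose-volume histogram (volume in cc receiving at least
#' each dose), returns the volume at an arbitrary dose level by linear
#' interpolation. Queries beyond the last grid dose return 0 cc (no volume
#' receives more than the maximum delivered dose).
#'
#' @param dose Ascending dose grid (cGy).
#' @param volume Cumulative volume (cc), non-increasing; `volume[1]` is the
#'   total structure volume.
#' @param dose_level Dose level(s), cGy, at which to evaluate (vectorized).
#' @return Volume(s) in cc.
#' @export
#' @examples
#' extract_index(c(0, 5000), c(30, 30), 4000)  # uniform 50 Gy to 30 cc -> 30
extract_index <- function(dose, volume, dose_level) {
  if (length(dose) == 0L) stop("empty DVH curve")
  if (length(dose) != length(volume)) stop("dose and volume lengths differ")
  if (is.unsorted(dose, strictly = TRUE)) stop("DVH dose grid must be strictly ascending")
  if (any(diff(volume) > 1e-9)) stop("cumulative DVH volume must be non-increasing")
  if (any(dose_level < 0)) stop("dose_level must be >= 0")
  out <- approx(dose, volume, xout = dose_level, rule = 2, ties = "ordered")$y
  out[dose_level > max(dose)] <- 0
  # below the first grid point the cumulative volume equals the total volume
  out[dose_level < min(dose)] <- volume[1]
  out
}

#' Read a per-patient DVH curve from a two-column CSV
#'
#' @param path CSV with columns `dose` (cGy, ascending) and `volume` (cc,
#'   cumulative, non-increasing).
#' @return Tibble with columns `dose`, `volume`.
#' @export
read_dvh <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("dose", "volume") %in% names(d))) stop("DVH file needs columns dose, volume")
  extract_index(d$dose, d$volume, d$dose[1])  # validates grid invariants
  tibble::as_tibble(d)
}

#' Binarize a dosimetric factor into a treatment indicator
#'
#' The causal estimand is defined for a thresholded exposure: patients whose
#' factor value is strictly above the threshold are "treated" (T = 1), ties
#' and lower values are controls (T = 0).
#'
#' @param data Cohort tibble.
#' @param factor Dosimetric factor column name.
#' @param threshold Cut value, in the factor's units.
#' @param require_both_arms If `TRUE`, error when either arm is empty
#'   (degenerate threshold).
#' @return Integer 0/1 vector aligned with the rows of `data`.
#' @export
#' @examples
#' binarize(tibble::tibble(V60Gy = c(1, 2, 3)), "V60Gy", 2)  # 0 0 1
binarize <- function(data, factor, threshold, require_both_arms = FALSE) {
  if (!factor %in% names(data)) stop("factor '", factor, "' not present in cohort")
  v <- data[[factor]]
  if (anyNA(v)) stop("factor '", factor, "' contains NA")
  t_vec <- as.integer(v > threshold)
  if (require_both_arms && (all(t_vec == 1L) || all(t_vec == 0L))) {
    stop("degenerate arm: threshold ", threshold, " leaves one arm of '",
         factor, "' empty")
  }
  t_vec
}

#' One-hot encode clinical covariates
#'
#' Continuous covariates (currently `age`) are passed through; categorical
#' covariates expand to one indicator column per observed level, with
#' `"MISSING"` as its own column. Level order is alphabetical with `MISSING`
#' last, so the design matrix is reproducible across runs.
#'
#' @param data Cohort tibble.
#' @param covariates Covariate column names; defaults to the schema attribute.
#' @return Numeric matrix with one row per patient.
#' @export
one_hot <- function(data, covariates = NULL) {
  covariates <- covariates %||% attr(data, "schema")$covariates
  if (is.null(covariates)) stop("no covariates given and no schema attribute found")
  cols <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.numeric(x)) {
      cols[[cv]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      x[is.na(x) | x == ""] <- MISSING_LEVEL
      lev <- sort(setdiff(unique(x), MISSING_LEVEL))
      if (MISSING_LEVEL %in% x) lev <- c(lev, MISSING_LEVEL)
      for (l in lev) cols[[paste0(cv, "=", l)]] <- as.numeric(x == l)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  mat
}
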