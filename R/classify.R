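#' Ordered diagnosis factor
#'
#' Diagnoses are an ordered categorical scale
#' `normal < osteopenia < osteoporosis`, so comparisons such as
#' `dx >= "osteopenia"` ("osteopenic or worse") work directly.
#'
#' @param x A character vector of category names.
#' @return An ordered factor with levels `normal`, `osteopenia`,
#'   `osteoporosis`.
#' @export
as_diagnosis <- function(x) {
  if (!all(is.na(x) | x %in% DIAGNOSIS_LEVELS)) {
    abort(sprintf("Diagnosis values must be one of: %s.",
                  paste(DIAGNOSIS_LEVELS, collapse = ", ")))
  }
  factor(x, levels = DIAGNOSIS_LEVELS, ordered = TRUE)
}

#' WHO/ISCD diagnosis per site and from the lowest T-score
#'
#' The WHO/ISCD thresholds: osteoporosis when the T-score is at or below
#' -2.5 (inclusive), osteopenia when it lies strictly between -2.5 and -1,
#' otherwise normal (a T-score of exactly -1 is normal).  `site_classify()`
#' applies them to individual T-scores; `who_classify()` applies them to
#' the *lowest* of a patient's three T-scores — the current clinical rule,
#' which discards the other two measurements.
#'
#' @param t For `site_classify()`, a numeric vector of single-site
#'   T-scores.  For `who_classify()`, a length-3 T-score vector
#'   (spine, femoral neck, total hip), a 3-column matrix, or a cohort data
#'   frame with columns `t_l1l4`, `t_fneck`, `t_thip`.
#' @return An ordered diagnosis factor (see [as_diagnosis()]), one element
#'   per T-score (`site_classify`) or per patient (`who_classify`).
#' @examples
#' who_classify(c(-1.0, -1.0, -1.0))   # normal
#' who_classify(c(-1.1,  1.5,  1.5))   # osteopenia
#' who_classify(c(-2.5,  0.0,  0.0))   # osteoporosis (boundary inclusive)
#' @export
who_classify <- function(t) {
  m <- tscore_matrix(t)
  site_classify(unname(pmin(m[, 1], m[, 2], m[, 3])))
}

#' @rdname who_classify
#' @export
site_classify <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    abort("T-scores must be finite and non-missing.")
  }
  as_diagnosis(ifelse(t <= -2.5, "osteoporosis",
                      ifelse(t < -1, "osteopenia", "normal")))
}

#' Congruence of the three per-site diagnoses
#'
#' Applies the WHO thresholds to each site separately and records whether
#' all three agree.  A patient is "congruent" exactly when the spine,
#' femoral neck and total hip T-scores all yield the same per-site
#' diagnosis; in that case `congruent_category` carries it (otherwise
#' `NA`).  Note that a patient is WHO-normal if and only if all three sites
#' are individually normal, so congruent-normal and WHO-normal coincide.
#'
#' @inheritParams who_classify
#' @return A tibble with one row per patient and columns `dx_l1l4`,
#'   `dx_fneck`, `dx_thip`, `congruent` (logical) and `congruent_category`.
#' @export
congruence <- function(t) {
  m <- tscore_matrix(t)
  d1 <- site_classify(m[, 1])
  d2 <- site_classify(m[, 2])
  d3 <- site_classify(m[, 3])
  cong <- d1 == d2 & d2 == d3
  tibble::tibble(
    dx_l1l4 = d1, dx_fneck = d2, dx_thip = d3,
    congruent = cong,
    congruent_category = as_diagnosis(ifelse(cong, as.character(d1), NA))
  )
}

#' Multivariate ellipsoid diagnosis
#'
#' The statistics-based alternative to the lowest-T-score rule: the three
#' T-scores are judged jointly by their Mahalanobis radius
#' `d = sqrt(t' R^{-1} t)` from the young-adult reference point, against
#' confidence ellipsoids whose boundary radii are constrained to the WHO
#' T-score magnitudes.  A patient on the low-BMD side (T-score sum `< 0`)
#' is osteoporotic when `d >= 2.5` (inclusive, mirroring `T <= -2.5`) and
#' osteopenic when `1 < d < 2.5` (strict, mirroring `-2.5 < T < -1`);
#' everyone else, including all patients with nonnegative T-score sum, is
#' normal.  The half-space gate makes exactly half of every exterior shell
#' count as diseased, so the rule's population rates are free of the
#' correlation structure.
#'
#' @inheritParams who_classify
#' @param model A [correlation_model()] for the three T-scores.
#' @param radii Length-2 increasing vector of threshold radii
#'   `c(r_osteopenia, r_osteoporosis)`; default `c(1, 2.5)`.
#' @return An ordered diagnosis factor, one element per patient.
#' @examples
#' ellipsoid_classify(c(-1, -1, -1), equicorrelation(0.6))   # osteopenia
#' ellipsoid_classify(c(-2.5, 0, 0), equicorrelation(0))     # osteoporosis
#' ellipsoid_classify(c(0.5, 0.5, 0.5), equicorrelation(0))  # normal
#' @export
ellipsoid_classify <- function(t, model, radii = c(1, 2.5)) {
  if (!is.numeric(radii) || length(radii) != 2L || any(radii <= 0) ||
      radii[1] >= radii[2]) {
    abort("`radii` must be two increasing positive radii.")
  }
  m <- tscore_matrix(t)
  d2 <- mahalanobis2(m, model)
  low <- rowSums(m) < 0
  as_diagnosis(ifelse(low & d2 >= radii[2]^2, "osteoporosis",
                      ifelse(low & d2 > radii[1]^2, "osteopenia", "normal")))
}

#' Classify a cohort by both diagnostic rules
#'
#' The workhorse verb: takes a cohort table of per-patient T-scores and
#' appends the WHO lowest-T-score diagnosis (`who_dx`), the multivariate
#' ellipsoid diagnosis (`ellipsoid_dx`), the squared Mahalanobis radius
#' (`d2`) and the three-site congruence flag (`congruent`).
#'
#' @param cohort A data frame with columns `t_l1l4`, `t_fneck`, `t_thip`
#'   (extra columns pass through untouched).
#' @param model A [correlation_model()]; when `NULL` (default) the Pearson
#'   correlations of the cohort's own T-scores are used, treating the
#'   T-scores as unit-variance in the reference scale.
#' @param radii Ellipsoid threshold radii, see [ellipsoid_classify()].
#' @param rule Which rule(s) to apply: `"both"` (default), `"who"` or
#'   `"ellipsoid"`.
#' @return `cohort` as a tibble with the appended columns.  An empty cohort
#'   returns an empty tibble with the same schema.
#' @seealso [diagnosis_counts()] for the category tallies,
#'   [compare_rules()] for the paired comparison.
#' @examples
#' simulate_cohort(n = 100, rho = 0.6, seed = 1) |>
#'   classify_cohort() |>
#'   diagnosis_counts()
#' @export
classify_cohort <- function(cohort, model = NULL, radii = c(1, 2.5),
                            rule = c("both", "who", "ellipsoid")) {
  rule <- match.arg(rule)
  out <- tibble::as_tibble(cohort)
  missing <- setdiff(TSCORE_COLS, names(out))
  if (length(missing) > 0) {
    abort(sprintf("Missing T-score column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(out) == 0) {
    if (rule != "ellipsoid") out$who_dx <- as_diagnosis(character())
    if (rule != "who") {
      out$ellipsoid_dx <- as_diagnosis(character())
      out$d2 <- numeric()
    }
    out$congruent <- logical()
    return(out)
  }
  m <- tscore_matrix(out)
  if (rule != "ellipsoid") out$who_dx <- who_classify(m)
  if (rule != "who") {
    model <- model %||% cohort_correlation(out)
    out$ellipsoid_dx <- ellipsoid_classify(m, model, radii)
    out$d2 <- mahalanobis2(m, model)
  }
  out$congruent <- congruence(m)$congruent
  out
}

#' Pearson correlation model of a cohort's own T-scores
#'
#' For real cohorts without an external young-adult correlation estimate,
#' the between-site correlations are taken from the cohort itself.
#'
#' @param cohort A data frame with the three T-score columns.
#' @return A [correlation_model()].
#' @export
cohort_correlation <- function(cohort) {
  m <- tscore_matrix(cohort)
  if (nrow(m) < 3) abort("Need at least 3 rows to estimate correlations.")
  r <- cor(m)
  correlation_model(r[1, 2], r[1, 3], r[2, 3])
}

#' Tally diagnoses by category
#'
#' Counts and percentages per diagnosis category for each diagnosis column
#' present in a classified cohort (output of [classify_cohort()]).  All
#' three categories always appear, with zero counts where absent.
#'
#' @param classified A tibble with columns `who_dx` and/or `ellipsoid_dx`.
#' @return A tibble with columns `rule`, `category`, `n`, `pct`.
#' @export
diagnosis_counts <- function(classified) {
  cols <- intersect(c("who_dx", "ellipsoid_dx"), names(classified))
  if (length(cols) == 0) {
    abort("`classified` has no diagnosis columns; run classify_cohort() first.")
  }
  total <- nrow(classified)
  purrr::map_dfr(cols, function(col) {
    tab <- table(factor(classified[[col]], levels = DIAGNOSIS_LEVELS))
    tibble::tibble(
      rule = sub("_dx$", "", col),
      category = as_diagnosis(DIAGNOSIS_LEVELS),
      n = as.integer(tab),
      pct = if (total > 0) 100 * as.integer(tab) / total else rep(NA_real_, 3)
    )
  })
}
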