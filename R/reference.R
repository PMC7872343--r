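#' Young-adult reference for one skeletal site
#'
#' A T-score expresses a patient's areal BMD as a number of young-adult
#' standard deviations below (negative) or above (positive) the young-adult
#' mean at the same site.  `site_reference()` bundles the mean and SD of the
#' young-adult reference population for one of the three standard DXA sites,
#' with an optional reference sample size (used by
#' [tscore_distribution()] to pick the degrees of freedom of the
#' multivariate-t model; `Inf` means the reference is treated as known).
#'
#' @param site One of `"L1L4"`, `"femoral_neck"`, `"total_hip"`.
#' @param mean_bmd Young-adult mean BMD in g/cm^2; must be positive.
#' @param sd_bmd Young-adult BMD standard deviation in g/cm^2; must be
#'   positive.
#' @param sample_size Size of the young-adult reference sample, a single
#'   number `>= 2`, or `Inf` (default) when the reference mean and SD are
#'   treated as known constants.
#'
#' @return An object of class `site_reference`.
#' @examples
#' ref <- site_reference("femoral_neck", mean_bmd = 0.858, sd_bmd = 0.12)
#' compute_tscore(0.558, ref)
#' @export
site_reference <- function(site, mean_bmd, sd_bmd, sample_size = Inf) {
  site <- match.arg(site, SITE_LABELS)
  check_number(mean_bmd, "mean_bmd")
  check_number(sd_bmd, "sd_bmd")
  if (mean_bmd <= 0) abort("`mean_bmd` must be positive (g/cm^2).")
  if (sd_bmd <= 0) abort("`sd_bmd` must be positive (g/cm^2).")
  check_number(sample_size, "sample_size", finite = FALSE)
  if (is.finite(sample_size) &&
      (sample_size < 2 || sample_size != round(sample_size))) {
    abort("`sample_size` must be an integer >= 2, or Inf.")
  }
  structure(
    list(site = site, mean_bmd = mean_bmd, sd_bmd = sd_bmd,
         sample_size = sample_size),
    class = "site_reference"
  )
}

#' @export
print.site_reference <- function(x, ...) {
  cat(sprintf("<site_reference> %s: mean %.4g g/cm^2, SD %.4g g/cm^2, n = %s\n",
              x$site, x$mean_bmd, x$sd_bmd,
              if (is.finite(x$sample_size)) format(x$sample_size) else "Inf"))
  invisible(x)
}

#' Three-site young-adult reference panel
#'
#' Bundles one [site_reference()] per DXA site together with the
#' between-site T-score correlation model.  Reference values differ by DXA
#' manufacturer (the hip sites usually come from NHANES III, L1-L4 from the
#' vendor), so the panel is always supplied by the user rather than shipped
#' with the package.
#'
#' @param l1l4,fneck,thip [site_reference()] objects for the L1-L4 spine,
#'   femoral neck and total hip respectively.
#' @param correlation A [correlation_model()] for the three T-scores.
#'
#' @return An object of class `reference_panel`.
#' @seealso [read_reference_panel()] to load a panel from a JSON or YAML
#'   config file, [add_tscores()] to convert a BMD cohort to T-scores.
#' @export
reference_panel <- function(l1l4, fneck, thip, correlation) {
  refs <- list(l1l4, fneck, thip)
  ok <- vapply(refs, inherits, logical(1), "site_reference")
  if (!all(ok)) abort("`l1l4`, `fneck` and `thip` must be site_reference objects.")
  sites <- vapply(refs, `[[`, character(1), "site")
  if (!identical(sites, SITE_LABELS)) {
    abort(sprintf("Panel sites must be %s in that order; got %s.",
                  paste(SITE_LABELS, collapse = ", "),
                  paste(sites, collapse = ", ")))
  }
  if (!inherits(correlation, "correlation_model")) {
    abort("`correlation` must be a correlation_model object.")
  }
  structure(list(refs = setNames(refs, SITE_LABELS), correlation = correlation),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>\n")
  for (r in x$refs) {
    cat("  "); print(r)
  }
  cat(sprintf("  correlations: rho12 = %.4f, rho13 = %.4f, rho23 = %.4f\n",
              x$correlation$rho12, x$correlation$rho13, x$correlation$rho23))
  invisible(x)
}

#' Load a reference panel from a JSON or YAML config
#'
#' The config maps each site to `{mean, sd}` (optionally `n`) and carries
#' the three correlations `rho12` (spine vs femoral neck), `rho13` (spine vs
#' total hip) and `rho23` (femoral neck vs total hip):
#'
#' ```yaml
#' L1L4:          {mean: 1.18, sd: 0.12}
#' femoral_neck:  {mean: 0.86, sd: 0.12}
#' total_hip:     {mean: 0.94, sd: 0.12}
#' correlation:   {rho12: 0.66, rho13: 0.61, rho23: 0.75}
#' ```
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  missing <- setdiff(c(SITE_LABELS, "correlation"), names(cfg))
  if (length(missing) > 0) {
    abort(sprintf("Reference config is missing entries: %s.",
                  paste(missing, collapse = ", ")))
  }
  mk <- function(site) {
    s <- cfg[[site]]
    site_reference(site, mean_bmd = s$mean, sd_bmd = s$sd,
                   sample_size = s$n %||% Inf)
  }
  rho <- cfg$correlation
  reference_panel(mk("L1L4"), mk("femoral_neck"), mk("total_hip"),
                  correlation_model(rho$rho12, rho$rho13, rho$rho23))
}

#' Convert BMD to a T-score and back
#'
#' `compute_tscore()` standardises a BMD measurement against its young-adult
#' site reference, `T = (BMD - mean) / SD`; `tscore_to_bmd()` inverts it.
#' Both are vectorised over the measurement.
#'
#' @param bmd Areal BMD in g/cm^2.
#' @param t A T-score (dimensionless, in young-adult SD units).
#' @param ref A [site_reference()].
#' @return A numeric vector: T-scores for `compute_tscore()`, BMD in g/cm^2
#'   for `tscore_to_bmd()`.
#' @examples
#' ref <- site_reference("L1L4", mean_bmd = 1.0, sd_bmd = 0.1)
#' compute_tscore(c(1.0, 0.75), ref)  # 0, -2.5
#' tscore_to_bmd(-2.5, ref)           # 0.75
#' @export
compute_tscore <- function(bmd, ref) {
  if (!inherits(ref, "site_reference")) abort("`ref` must be a site_reference.")
  (bmd - ref$mean_bmd) / ref$sd_bmd
}

#' @rdname compute_tscore
#' @export
tscore_to_bmd <- function(t, ref) {
  if (!inherits(ref, "site_reference")) abort("`ref` must be a site_reference.")
  ref$mean_bmd + t * ref$sd_bmd
}

#' Attach T-score columns to a BMD cohort
#'
#' Takes a cohort with raw BMD columns `bmd_l1l4`, `bmd_fneck`, `bmd_thip`
#' and a [reference_panel()], and appends the standard T-score columns
#' `t_l1l4`, `t_fneck`, `t_thip` so the cohort can flow into
#' [classify_cohort()].
#'
#' @param data A data frame with the three `bmd_*` columns.
#' @param panel A [reference_panel()].
#' @return `data` as a tibble with the three `t_*` columns appended.
#' @export
add_tscores <- function(data, panel) {
  if (!inherits(panel, "reference_panel")) {
    abort("`panel` must be a reference_panel.")
  }
  bmd_cols <- c("bmd_l1l4", "bmd_fneck", "bmd_thip")
  missing <- setdiff(bmd_cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Missing BMD column(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  for (i in seq_along(bmd_cols)) {
    out[[TSCORE_COLS[i]]] <- compute_tscore(out[[bmd_cols[i]]],
                                            panel$refs[[i]])
  }
  out
}
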