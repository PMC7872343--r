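#' Read and write cohort CSV files
#'
#' Cohort files are plain UTF-8 CSV with a header, period decimal
#' separator, and at least the columns `patient_id`, `t_l1l4`, `t_fneck`,
#' `t_thip`; extra columns (e.g. `frax_major`, `frax_hip`, covariate
#' flags) pass through.  Unicode minus signs (as pasted from reports) are
#' normalised to ASCII on input.  Writing preserves doubles at full
#' precision, so a write/read round trip is lossless well beyond 12
#' significant digits.
#'
#' @param path File path.
#' @param cohort A cohort data frame.
#' @return `read_cohort_csv()` returns a tibble (possibly with 0 rows when
#'   the file holds only a header); `write_cohort_csv()` returns `path`
#'   invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cohort file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Cohort file %s is missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  numeric_cols <- c(TSCORE_COLS,
                    grep("^frax_", names(raw), value = TRUE))
  for (col in setdiff(names(raw), "patient_id")) {
    txt <- gsub("−", "-", raw[[col]])  # unicode minus -> hyphen-minus
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad) > 0) {
      if (col %in% numeric_cols) {
        abort(sprintf(
          "Non-numeric value \"%s\" in column %s of %s (data line %d).",
          txt[bad[1]], col, path, bad[1]))
      }
      # covariate columns may be logical flags or labels
      raw[[col]] <- readr::parse_guess(txt)
    } else {
      raw[[col]] <- val
    }
  }
  if (nrow(raw) > 0) {
    if (anyDuplicated(raw$patient_id)) {
      abort(sprintf("Duplicate patient_id values in %s.", path))
    }
    tmat <- as.matrix(raw[TSCORE_COLS])
    if (anyNA(tmat) || any(!is.finite(tmat))) {
      abort(sprintf("Missing or non-finite T-scores in %s.", path))
    }
  }
  raw
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(TSCORE_COLS, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("Missing T-score column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' Surface mesh of a diagnostic confidence ellipsoid
#'
#' Points on the ellipsoid `{t : t' R^{-1} t = radius^2}`, for plotting the
#' diagnostic boundary in T-score space.  The unit sphere is parameterised
#' by `resolution` polar x `resolution` azimuthal angles and mapped through
#' `radius * R^{1/2}` (symmetric square root), so every emitted point
#' satisfies the quadratic-form constraint to numerical precision.
#'
#' @param model A [correlation_model()].
#' @param radius Ellipsoid radius on the Mahalanobis scale; the diagnostic
#'   boundaries use 2.5 (osteoporosis) and 1.0 (osteopenia).
#' @param resolution Number of subdivisions per angle, at least 8; the mesh
#'   has `resolution^2` points.
#' @return A tibble with columns `x`, `y`, `z` (T-score units, site order
#'   spine / femoral neck / total hip) plus the generating angles `theta`,
#'   `phi`.
#' @examples
#' mesh <- ellipsoid_mesh(equicorrelation(0.8), radius = 2.5)
#' range(mahalanobis2(as.matrix(mesh[, 1:3]), equicorrelation(0.8)))
#' @export
ellipsoid_mesh <- function(model, radius = 2.5, resolution = 24) {
  R <- model_matrix(model)
  check_number(radius, "radius")
  if (radius <= 0) abort("`radius` must be positive.")
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 8 || resolution != round(resolution)) {
    abort("`resolution` must be an integer >= 8.")
  }
  theta <- seq(0, pi, length.out = resolution)          # polar, poles included
  phi <- seq(0, 2 * pi, length.out = resolution + 1)[-(resolution + 1)]
  grid <- tidyr::expand_grid(theta = theta, phi = phi)
  u <- cbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  p <- radius * (u %*% sym_sqrt(R))   # symmetric sqrt: no transpose needed
  tibble::tibble(x = p[, 1], y = p[, 2], z = p[, 3],
                 theta = grid$theta, phi = grid$phi)
}
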