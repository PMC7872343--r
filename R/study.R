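#' Simulation grid comparing the two diagnostic rules
#'
#' Runs the full simulation experiment: for each equicorrelation level in
#' `rho_grid`, a cohort of `n` standard-normal T-score triples is generated
#' with common random numbers (the same seed, hence the same underlying iid
#' draws, at every level), both diagnostic rules are applied against the
#' matching correlation model, and the three-site congruence is tallied.
#'
#' Two structural facts show up in the output.  First, the congruent-normal
#' count always equals the WHO-normal count, because a WHO-normal patient
#' is exactly one whose three sites are all individually normal.  Second,
#' with the default symmetric-square-root transform, the ellipsoid rule's
#' counts are identical in every column: under common random numbers the
#' Mahalanobis radius reduces to the radius of the shared iid draws, and
#' the sign of the T-score sum is likewise invariant, so changing the
#' correlation moves only the WHO counts.
#'
#' @param n Patients per correlation level (default 1000).
#' @param rho_grid Equicorrelation levels (default `c(0, .2, .4, .6, .8)`).
#' @param seed Integer RNG seed shared by all levels, or `NULL`.
#' @param radii Ellipsoid threshold radii (see [ellipsoid_classify()]).
#' @param transform Matrix square root used by the generator (see
#'   [simulation_config()]).
#' @return A `table3_report`: a tibble with columns `rho`, `rule`
#'   (`congruent`, `who`, `ellipsoid`), `category`, `n` and `pct`, with the
#'   run's `n` and `seed` as attributes.
#' @examples
#' run_table3(n = 500, seed = 7)
#' @export
run_table3 <- function(n = 1000, rho_grid = RHO_GRID, seed = NULL,
                       radii = c(1, 2.5),
                       transform = c("symmetric_sqrt", "cholesky")) {
  transform <- match.arg(transform)
  if (!is.numeric(rho_grid) || length(rho_grid) < 1) {
    abort("`rho_grid` must be a numeric vector of equicorrelation levels.")
  }
  rows <- purrr::map_dfr(rho_grid, function(rho) {
    model <- equicorrelation(rho)
    cohort <- simulate_cohort(n = n, correlation = model, seed = seed,
                              transform = transform)
    cls <- classify_cohort(cohort, model = model, radii = radii)
    cong <- congruence(cls)
    cong_tab <- table(factor(cong$congruent_category,
                             levels = DIAGNOSIS_LEVELS))
    counts <- diagnosis_counts(cls)
    dplyr::bind_rows(
      tibble::tibble(rule = "congruent",
                     category = as_diagnosis(DIAGNOSIS_LEVELS),
                     n = as.integer(cong_tab),
                     pct = 100 * as.integer(cong_tab) / nrow(cls)),
      counts
    ) |>
      dplyr::mutate(rho = rho, .before = 1)
  })
  structure(rows, class = c("table3_report", class(rows)),
            n = n, seed = seed, radii = radii, transform = transform)
}

#' @export
print.table3_report <- function(x, ...) {
  cat(sprintf("Simulated diagnosis grid: n = %d per column, seed = %s\n\n",
              attr(x, "n"),
              if (is.null(attr(x, "seed"))) "<none>" else attr(x, "seed")))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(tibble::as_tibble(x),
                  cell = sprintf("%d (%.1f%%)", .data$n, .data$pct)),
    id_cols = c("rule", "category"),
    names_from = "rho", values_from = "cell", names_prefix = "rho="
  )
  print(wide, n = Inf)
  invisible(x)
}

#' Write a simulation grid report as TSV
#'
#' One row per (rule, category), one column pair (`n`, `pct`) per
#' correlation level, mirroring the wide layout of the printed grid.
#'
#' @param report A `table3_report` from [run_table3()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table3_tsv <- function(report, path) {
  if (!inherits(report, "table3_report")) {
    abort("`report` must come from run_table3().")
  }
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(report),
    id_cols = c("rule", "category"),
    names_from = "rho", values_from = c("n", "pct"),
    names_glue = "rho{rho}_{.value}"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}

#' McNemar's test on a discordant pair count
#'
#' Paired comparison of two dichotomised diagnostic rules on the same
#' patients: with `b` patients positive only under rule A and `c` positive
#' only under rule B, the test statistic is `(b - c)^2 / (b + c)` (no
#' continuity correction) referred to a chi-squared distribution with 1 df.
#' Concordant pairs carry no information and do not enter.
#'
#' @param b,c Nonnegative discordant counts; `b + c` must be at least 1.
#' @return An object of class `mcnemar_test` with fields `b`, `c`,
#'   `statistic`, `p.value`; has [tidy()] and [glance()] methods.
#' @examples
#' mcnemar_test(b = 10, c = 2)   # chi2 = 64/12
#' @export
mcnemar_test <- function(b, c) {
  for (nm in c("b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      abort(sprintf("`%s` must be a nonnegative integer count.", nm))
    }
  }
  if (b + c == 0) {
    abort("McNemar's test is undefined with no discordant pairs (b + c = 0).")
  }
  chi2 <- (b - c)^2 / (b + c)
  structure(list(b = b, c = c, statistic = chi2,
                 p.value = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "mcnemar_test")
}

#' @export
print.mcnemar_test <- function(x, ...) {
  cat(sprintf("McNemar's test (no continuity correction)\n  discordant pairs: b = %d, c = %d\n  chi-squared = %.4g, df = 1, p = %.4g\n",
              x$b, x$c, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.mcnemar_test <- function(x, ...) {
  tibble::tibble(b = x$b, c = x$c, statistic = x$statistic,
                 df = 1, p.value = x$p.value,
                 method = "McNemar (uncorrected)")
}

#' @export
glance.mcnemar_test <- function(x, ...) tidy(x)

#' Paired comparison of the WHO and ellipsoid rules on one cohort
#'
#' Classifies every patient by both rules, cross-tabulates the two
#' diagnoses, and runs McNemar's test on the two clinically relevant
#' dichotomisations: osteoporosis vs not, and disease (osteopenia or
#' worse) vs normal.
#'
#' @inheritParams classify_cohort
#' @return An object of class `rule_comparison` with fields
#'   `crosstab` (3x3 tibble of counts, WHO rows by ellipsoid columns),
#'   `counts` (per-rule tallies, see [diagnosis_counts()]),
#'   `osteoporosis` and `disease` ([mcnemar_test()] objects, with `b` = WHO
#'   positive only, `c` = ellipsoid positive only), and `n`.  Has
#'   [tidy()] and [glance()] methods.
#' @examples
#' emulate_real_cohort(seed = 3) |> compare_rules()
#' @export
compare_rules <- function(cohort, model = NULL, radii = c(1, 2.5)) {
  cls <- classify_cohort(cohort, model = model, radii = radii)
  if (nrow(cls) == 0) abort("`cohort` is empty.")
  crosstab <- cls |>
    dplyr::count(.data$who_dx, .data$ellipsoid_dx, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "ellipsoid_dx", values_from = "n",
                       names_prefix = "ellipsoid_", values_fill = 0L)
  pair_test <- function(who_pos, ell_pos) {
    b <- sum(who_pos & !ell_pos)
    c <- sum(!who_pos & ell_pos)
    if (b + c == 0) NULL else mcnemar_test(b, c)
  }
  op <- pair_test(cls$who_dx == "osteoporosis",
                  cls$ellipsoid_dx == "osteoporosis")
  dis <- pair_test(cls$who_dx >= "osteopenia",
                   cls$ellipsoid_dx >= "osteopenia")
  structure(list(crosstab = crosstab, counts = diagnosis_counts(cls),
                 osteoporosis = op, disease = dis, n = nrow(cls)),
            class = "rule_comparison")
}

#' @export
print.rule_comparison <- function(x, ...) {
  cat(sprintf("WHO vs ellipsoid rule on %d patients\n\nCross-tabulation (WHO rows, ellipsoid columns):\n", x$n))
  print(x$crosstab)
  for (nm in c("osteoporosis", "disease")) {
    cat(sprintf("\n%s dichotomisation:\n",
                if (nm == "disease") "Osteopenia-or-worse" else "Osteoporosis"))
    if (is.null(x[[nm]])) cat("  rules agree everywhere (no discordant pairs)\n")
    else print(x[[nm]])
  }
  invisible(x)
}

#' @export
tidy.rule_comparison <- function(x, ...) {
  purrr::map_dfr(c("osteoporosis", "disease"), function(nm) {
    if (is.null(x[[nm]])) {
      tibble::tibble(comparison = nm, b = 0L, c = 0L, statistic = NA_real_,
                     df = 1, p.value = NA_real_,
                     method = "McNemar (uncorrected)")
    } else {
      dplyr::mutate(tidy(x[[nm]]), comparison = nm, .before = 1)
    }
  })
}

#' @export
glance.rule_comparison <- function(x, ...) {
  cnt <- function(rule, category) {
    x$counts$n[x$counts$rule == rule & x$counts$category == category]
  }
  tibble::tibble(
    n = x$n,
    who_osteoporosis = cnt("who", "osteoporosis"),
    ellipsoid_osteoporosis = cnt("ellipsoid", "osteoporosis"),
    excess_osteoporosis = cnt("ellipsoid", "osteoporosis") -
      cnt("who", "osteoporosis"),
    chi2_osteoporosis = if (is.null(x$osteoporosis)) NA_real_
                        else x$osteoporosis$statistic,
    chi2_disease = if (is.null(x$disease)) NA_real_ else x$disease$statistic
  )
}

#' Compare FRAX risks between ellipsoid-reclassified groups
#'
#' Among patients the WHO rule calls osteopenic, some are reclassified as
#' osteoporotic by the ellipsoid rule.  This compares the 10-year FRAX
#' fracture risks (consumed as input columns, never computed) between the
#' reclassified and non-reclassified groups with Welch's two-sample t-test,
#' one outcome per row.
#'
#' @inheritParams classify_cohort
#' @param outcomes Names of the FRAX risk columns to compare (percent).
#' @param within WHO category whose patients form the comparison frame
#'   (default `"osteopenia"`, the clinically interesting reclassification).
#' @return A tibble with one row per outcome: group means (`mean_reclassified`,
#'   `mean_other`), group sizes, and the two-sided Welch `p.value`.
#' @export
frax_group_compare <- function(cohort, model = NULL, radii = c(1, 2.5),
                               outcomes = c("frax_major", "frax_hip"),
                               within = "osteopenia") {
  missing <- setdiff(outcomes, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("Missing FRAX column(s): %s.", paste(missing, collapse = ", ")))
  }
  cls <- classify_cohort(cohort, model = model, radii = radii)
  frame <- dplyr::filter(cls, .data$who_dx == within)
  reclass <- frame$ellipsoid_dx == "osteoporosis"
  if (sum(reclass) == 0) {
    abort("The reclassified group (ellipsoid-osteoporotic) is empty.")
  }
  if (sum(!reclass) == 0) {
    abort("The non-reclassified group is empty.")
  }
  purrr::map_dfr(outcomes, function(col) {
    x <- frame[[col]][reclass]
    y <- frame[[col]][!reclass]
    if (isTRUE(all.equal(c(x, y), rep(mean(c(x, y)), length(x) + length(y))))) {
      # degenerate: identical constant risks in both groups
      return(tibble::tibble(outcome = col, mean_reclassified = mean(x),
                            mean_other = mean(y), n_reclassified = length(x),
                            n_other = length(y), statistic = 0,
                            p.value = 1))
    }
    tt <- t.test(x, y)
    tibble::tibble(outcome = col, mean_reclassified = mean(x),
                   mean_other = mean(y), n_reclassified = length(x),
                   n_other = length(y),
                   statistic = unname(tt$statistic),
                   p.value = tt$p.value)
  })
}
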