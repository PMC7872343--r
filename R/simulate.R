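#' Simulation configuration for synthetic T-score cohorts
#'
#' Collects the parameters of one synthetic DXA cohort: size, between-site
#' correlation structure, per-site means and SDs on the T-score scale, the
#' RNG seed, and the matrix-square-root transform used to correlate the
#' draws.  The defaults are the simulation study's conditions: 1000
#' patients whose T-scores are marginally standard normal (the simulated
#' population equals the young-adult reference), correlated by a single
#' equicorrelation.
#'
#' @param n Cohort size (default 1000).
#' @param rho Equicorrelation in (-0.5, 1); ignored when `correlation` is
#'   supplied.
#' @param correlation Optional full [correlation_model()] overriding `rho`.
#' @param means,sds Per-site T-score means and SDs (length 3, site order
#'   spine / femoral neck / total hip).  Defaults 0 and 1.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @param transform `"symmetric_sqrt"` (default) or `"cholesky"`: how the
#'   correlation matrix is factored before mixing the iid normal draws.
#'   The symmetric (eigendecomposition) square root has the property that,
#'   under common random numbers, both the Mahalanobis radius and the sign
#'   of the T-score sum are identical across equicorrelation levels, so the
#'   ellipsoid rule's counts do not move as the correlation changes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n = 1000, rho = 0, correlation = NULL,
                              means = c(0, 0, 0), sds = c(1, 1, 1),
                              seed = NULL,
                              transform = c("symmetric_sqrt", "cholesky")) {
  transform <- match.arg(transform)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  correlation <- correlation %||% equicorrelation(rho)
  if (!inherits(correlation, "correlation_model")) {
    abort("`correlation` must be a correlation_model.")
  }
  if (!is.numeric(means) || length(means) != 3L || anyNA(means)) {
    abort("`means` must be a length-3 numeric vector.")
  }
  if (!is.numeric(sds) || length(sds) != 3L || anyNA(sds) || any(sds <= 0)) {
    abort("`sds` must be three positive numbers.")
  }
  structure(list(n = as.integer(n), correlation = correlation,
                 means = as.numeric(means), sds = as.numeric(sds),
                 seed = seed, transform = transform),
            class = "simulation_config")
}

#' Simulate a cohort of trivariate normal T-score vectors
#'
#' Draws `n` patients whose T-score triples (L1-L4 spine, femoral neck,
#' total hip) are trivariate normal: iid standard normal draws `z` are
#' correlated through a matrix square root `S` of the correlation matrix
#' (`t = means + sds * (S z)` componentwise).  With a fixed `seed` the
#' output is bit-reproducible, and because the same seed yields the same
#' `z` whatever the correlation, cohorts generated at different
#' correlations share common random numbers.
#'
#' @param n,rho,correlation,means,sds,seed,transform See
#'   [simulation_config()]; ignored when `config` is supplied.
#' @param config Optionally, a ready-made [simulation_config()].
#' @return A tibble with columns `patient_id`, `t_l1l4`, `t_fneck`,
#'   `t_thip`.
#' @examples
#' simulate_cohort(n = 5, rho = 0.8, seed = 42)
#' @export
simulate_cohort <- function(n = 1000, rho = 0, correlation = NULL,
                            means = c(0, 0, 0), sds = c(1, 1, 1),
                            seed = NULL,
                            transform = c("symmetric_sqrt", "cholesky"),
                            config = NULL) {
  cfg <- config %||% simulation_config(n, rho, correlation, means, sds,
                                       seed, match.arg(transform))
  if (!inherits(cfg, "simulation_config")) {
    abort("`config` must come from simulation_config().")
  }
  R <- cfg$correlation$matrix
  S <- switch(cfg$transform,
              symmetric_sqrt = sym_sqrt(R),
              cholesky = t(chol(R)))
  z <- with_seed_(cfg$seed, matrix(rnorm(cfg$n * 3L), nrow = cfg$n))
  x <- z %*% t(S)
  t <- sweep(sweep(x, 2, cfg$sds, `*`), 2, cfg$means, `+`)
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(cfg$n)),
    t_l1l4 = t[, 1], t_fneck = t[, 2], t_thip = t[, 3]
  )
}

#' Emulate a realistic screening cohort
#'
#' Generates a synthetic stand-in for a screening population of 1000
#' 65-year-old women: trivariate normal T-scores with site means
#' (-0.90, -1.54, -0.97), SDs (1.50, 0.93, 1.04) and between-site
#' correlations (0.6558, 0.6145, 0.7508) — summary statistics typical of a
#' real DXA screening cohort.  Optionally attaches Bernoulli clinical
#' covariates (diabetes 7.1%, prior adult fracture 2.4%, calcium/vitamin D
#' supplementation 60.3%) and *synthetic* 10-year FRAX risk columns.
#'
#' The FRAX columns are generated, not computed: FRAX itself is a
#' proprietary clinical calculator whose outputs this package only ever
#' consumes.  The synthetic model is log-normal in the femoral neck
#' T-score, `frax_major = exp(1.9 - 0.4 t_fneck + e)` and
#' `frax_hip = exp(-0.85 - 0.9 t_fneck + e')` (percent, `e` Gaussian
#' noise), chosen so that lower femoral-neck BMD means higher risk and the
#' cohort means land in the clinically familiar ranges (roughly 12% major,
#' 1.7% hip).  Use them to exercise [frax_group_compare()], not as
#' clinical estimates.
#'
#' @param n Cohort size (default 1000).
#' @param seed Integer RNG seed or `NULL`.
#' @param covariates Attach the Bernoulli covariate columns `diabetes`,
#'   `prior_fx`, `supplement`? Default `TRUE`.
#' @param frax Attach synthetic `frax_major`, `frax_hip` columns (percent)?
#'   Default `TRUE`.
#' @return A cohort tibble (see [simulate_cohort()]) with the extra
#'   columns.
#' @export
emulate_real_cohort <- function(n = 1000, seed = NULL, covariates = TRUE,
                                frax = TRUE) {
  with_seed_(seed, {
    out <- simulate_cohort(
      n = n,
      correlation = correlation_model(0.6558, 0.6145, 0.7508),
      means = c(-0.90, -1.54, -0.97),
      sds = c(1.50, 0.93, 1.04)
    )
    if (covariates) {
      out$diabetes <- runif(n) < 0.071
      out$prior_fx <- runif(n) < 0.024
      out$supplement <- runif(n) < 0.603
    }
    if (frax) {
      out$frax_major <- exp(1.9 - 0.4 * out$t_fneck + rnorm(n, sd = 0.20))
      out$frax_hip <- exp(-0.85 - 0.9 * out$t_fneck + rnorm(n, sd = 0.30))
    }
    out
  })
}
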