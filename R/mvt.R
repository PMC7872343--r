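#' Between-site T-score correlation model
#'
#' The three DXA T-scores (L1-L4 spine, femoral neck, total hip) measured in
#' the same patient are strongly correlated.  `correlation_model()` stores
#' the three pairwise correlations and the implied 3x3 correlation matrix
#' (unit diagonal, symmetric, positive definite); `equicorrelation()` is the
#' common special case with all three correlations equal,
#' `R = (1 - rho) I + rho J`.
#'
#' Index convention: 1 = L1-L4 spine, 2 = femoral neck, 3 = total hip, so
#' `rho12` is spine vs femoral neck, `rho13` spine vs total hip, `rho23`
#' femoral neck vs total hip.
#'
#' @param rho12,rho13,rho23 Pairwise correlations, each in (-1, 1).
#' @param rho A single equicorrelation value in (-0.5, 1) (positive
#'   definiteness of the 3x3 equicorrelated matrix requires rho > -1/2).
#'
#' @return An object of class `correlation_model` with fields `rho12`,
#'   `rho13`, `rho23` and `matrix`.
#' @examples
#' equicorrelation(0.8)
#' correlation_model(0.6558, 0.6145, 0.7508)  # a realistic adult cohort
#' @export
correlation_model <- function(rho12, rho13, rho23) {
  for (nm in c("rho12", "rho13", "rho23")) {
    v <- get(nm)
    check_number(v, nm)
    if (abs(v) >= 1) abort(sprintf("`%s` must lie strictly in (-1, 1).", nm))
  }
  m <- matrix(c(1, rho12, rho13,
                rho12, 1, rho23,
                rho13, rho23, 1), nrow = 3, byrow = TRUE,
              dimnames = list(SITE_LABELS, SITE_LABELS))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("The implied correlation matrix is not positive definite.")
  }
  structure(list(rho12 = rho12, rho13 = rho13, rho23 = rho23, matrix = m),
            class = "correlation_model")
}

#' @rdname correlation_model
#' @export
equicorrelation <- function(rho) {
  correlation_model(rho, rho, rho)
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> rho12 = %.4f, rho13 = %.4f, rho23 = %.4f\n",
              x$rho12, x$rho13, x$rho23))
  invisible(x)
}

# Accept a correlation_model or a bare positive-definite matrix.
model_matrix <- function(model) {
  if (inherits(model, "correlation_model")) return(model$matrix)
  if (is.matrix(model) && all(dim(model) == c(3, 3))) {
    ev <- eigen((model + t(model)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 1e-10) abort("`model` matrix is not positive definite.")
    return(model)
  }
  abort("`model` must be a correlation_model or a 3x3 positive-definite matrix.")
}

# Symmetric (eigendecomposition) matrix square root of a positive-definite
# matrix; the default cohort-generation transform.
sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Squared Mahalanobis distance of a T-score vector
#'
#' The covariance-standardised squared radius
#' `d^2 = (t - center)' R^{-1} (t - center)` of one or more T-score vectors
#' under a correlation model.  Under the zero-centered trivariate normal
#' model, `d^2` follows a chi-squared distribution with 3 degrees of freedom
#' regardless of the correlations; the ellipsoid classifier thresholds
#' `d = sqrt(d^2)` at the WHO T-score magnitudes 1.0 and 2.5.
#'
#' @param t A length-3 T-score vector (spine, femoral neck, total hip), a
#'   3-column matrix of such vectors, or a cohort data frame with columns
#'   `t_l1l4`, `t_fneck`, `t_thip`.
#' @param model A [correlation_model()] (or 3x3 positive-definite matrix).
#' @param center Center of the ellipsoid family; defaults to the T-score
#'   origin, i.e. the young-adult reference point.
#' @return A numeric vector of squared distances, one per row of `t`.
#' @examples
#' mahalanobis2(c(-2.5, 0, 0), equicorrelation(0))      # 6.25
#' mahalanobis2(c(-1, -1, -1), equicorrelation(0.6))    # 3 / 2.2
#' @export
mahalanobis2 <- function(t, model, center = c(0, 0, 0)) {
  m <- tscore_matrix(t)
  R <- model_matrix(model)
  as.numeric(stats::mahalanobis(m, center, R))
}

#' Multivariate model for a T-score vector
#'
#' The joint distribution of the three T-scores.  When the young-adult
#' reference mean and SD are treated as known (`reference_n = Inf`, the
#' default) the T-score vector is trivariate normal with correlation matrix
#' `R`.  When they were estimated from a finite young-adult sample of size
#' `m`, standardising by the *estimated* mean and SD makes each T-score a
#' location/scale Student-t quantity: the joint law is a trivariate t with
#' `nu = m - 1` degrees of freedom and scale matrix `((m + 1) / m) R`, which
#' recovers the normal model as `m -> Inf`.
#'
#' @param model A [correlation_model()].
#' @param center Length-3 location vector; defaults to the origin (the
#'   young-adult reference point).
#' @param reference_n Young-adult reference sample size `m` (`>= 3`) or
#'   `Inf` for the normal limit.
#'
#' @return An object of class `tscore_distribution` with fields `center`,
#'   `scale` (3x3), `dof` (`m - 1` or `Inf`) and `reference_n`.
#' @seealso [dtscore()], [marginal_distribution()],
#'   [conditional_distribution()], [category_coverage()]
#' @export
tscore_distribution <- function(model, center = c(0, 0, 0),
                                reference_n = Inf) {
  R <- model_matrix(model)
  if (!is.numeric(center) || length(center) != 3L || anyNA(center)) {
    abort("`center` must be a finite length-3 numeric vector.")
  }
  check_number(reference_n, "reference_n", finite = FALSE)
  if (reference_n < 3) abort("`reference_n` must be >= 3 (or Inf).")
  if (is.finite(reference_n)) {
    dof <- reference_n - 1
    scale <- ((reference_n + 1) / reference_n) * R
  } else {
    dof <- Inf
    scale <- R
  }
  structure(list(center = as.numeric(center), scale = scale, dof = dof,
                 reference_n = reference_n),
            class = "tscore_distribution")
}

#' @export
print.tscore_distribution <- function(x, ...) {
  cat(sprintf("<tscore_distribution> center (%.3g, %.3g, %.3g), dof = %s\n",
              x$center[1], x$center[2], x$center[3],
              if (is.finite(x$dof)) format(x$dof) else "Inf"))
  invisible(x)
}

#' Joint density of a T-score vector
#'
#' Density of the trivariate Student-t (finite `dof`) or trivariate normal
#' (`dof = Inf`) model from [tscore_distribution()], evaluated rowwise.
#'
#' @param x A length-3 vector, 3-column matrix, or cohort data frame of
#'   T-score vectors.
#' @param dist A [tscore_distribution()].
#' @return Numeric vector of densities.
#' @export
dtscore <- function(x, dist) {
  stopifnot(inherits(dist, "tscore_distribution"))
  m <- tscore_matrix(x)
  p <- 3
  S <- dist$scale
  detS <- det(S)
  d2 <- stats::mahalanobis(m, dist$center, S)
  nu <- dist$dof
  if (is.finite(nu)) {
    logc <- lgamma((nu + p) / 2) - lgamma(nu / 2) -
      (p / 2) * log(nu * pi) - 0.5 * log(detS)
    exp(logc - ((nu + p) / 2) * log1p(d2 / nu))
  } else {
    exp(-(p / 2) * log(2 * pi) - 0.5 * log(detS) - d2 / 2)
  }
}

# Univariate location/scale Student-t (df = Inf means normal); the common
# currency of the marginal and conditional laws.
new_tdist1 <- function(df, location, scale) {
  stopifnot(scale > 0)
  structure(list(df = df, location = location, scale = scale),
            class = "tdist1")
}

#' @export
print.tdist1 <- function(x, ...) {
  fam <- if (is.finite(x$df)) sprintf("t (df = %g)", x$df) else "normal"
  cat(sprintf("<tdist1> %s, location %.6g, scale %.6g\n",
              fam, x$location, x$scale))
  invisible(x)
}

#' Density, distribution and quantile of a univariate T-score law
#'
#' Helpers for the `tdist1` objects returned by [marginal_distribution()]
#' and [conditional_distribution()]: a location/scale Student-t when the
#' degrees of freedom are finite, a normal otherwise.
#'
#' @param x,q,p Numeric vectors of evaluation points / probabilities.
#' @param dist A `tdist1` object.
#' @return A numeric vector.
#' @export
dtdist1 <- function(x, dist) {
  stopifnot(inherits(dist, "tdist1"))
  z <- (x - dist$location) / dist$scale
  if (is.finite(dist$df)) dt(z, dist$df) / dist$scale else dnorm(z) / dist$scale
}

#' @rdname dtdist1
#' @export
ptdist1 <- function(q, dist) {
  stopifnot(inherits(dist, "tdist1"))
  z <- (q - dist$location) / dist$scale
  if (is.finite(dist$df)) pt(z, dist$df) else pnorm(z)
}

#' @rdname dtdist1
#' @export
qtdist1 <- function(p, dist) {
  stopifnot(inherits(dist, "tdist1"))
  z <- if (is.finite(dist$df)) qt(p, dist$df) else qnorm(p)
  dist$location + dist$scale * z
}

#' Marginal distribution of a single T-score
#'
#' Under the joint multivariate-t (or normal) model, each single-site
#' T-score is marginally a univariate Student-t (or normal) with the same
#' degrees of freedom, location `center[i]` and scale `sqrt(scale[i, i])`.
#'
#' @param dist A [tscore_distribution()].
#' @param site Site index 1 (L1-L4 spine), 2 (femoral neck) or 3 (total
#'   hip), or the corresponding label.
#' @return A `tdist1` object (see [dtdist1()]).
#' @export
marginal_distribution <- function(dist, site) {
  stopifnot(inherits(dist, "tscore_distribution"))
  i <- site_index(site)
  new_tdist1(dist$dof, dist$center[i], sqrt(dist$scale[i, i]))
}

site_index <- function(site) {
  if (is.character(site)) site <- match(site, SITE_LABELS)
  if (!is.numeric(site) || length(site) != 1L || is.na(site) ||
      !(site %in% 1:3)) {
    abort("`site` must be 1, 2, 3 or one of \"L1L4\", \"femoral_neck\", \"total_hip\".")
  }
  as.integer(site)
}

#' Conditional distribution of one T-score given the other two
#'
#' The standard multivariate-t conditioning formulas: writing the target as
#' block 1 and the two observed sites as block 2, the conditional law of the
#' target is univariate Student-t with degrees of freedom `nu + 2`, location
#' `mu1 + S12 S22^{-1} (x2 - mu2)`, and squared scale
#' `S11.2 (nu + d2^2) / (nu + 2)` where `S11.2 = S11 - S12 S22^{-1} S21` is
#' the Schur complement and `d2^2` the Mahalanobis distance of the observed
#' block.  In the normal limit (`nu = Inf`) the scale inflation disappears
#' and the familiar normal-theory conditional is returned.
#'
#' @param dist A [tscore_distribution()].
#' @param target Site index or label of the T-score being predicted.
#' @param observed Named or positional numeric vector of length 2 with the
#'   T-scores at the other two sites, in increasing site order.
#' @return A `tdist1` object (see [dtdist1()]).
#' @examples
#' d <- tscore_distribution(equicorrelation(0.6))
#' conditional_distribution(d, 1, c(-2, -2))
#' @export
conditional_distribution <- function(dist, target, observed) {
  stopifnot(inherits(dist, "tscore_distribution"))
  i <- site_index(target)
  j <- setdiff(1:3, i)
  if (!is.numeric(observed) || length(observed) != 2L || anyNA(observed) ||
      any(!is.finite(observed))) {
    abort("`observed` must be two finite T-scores (the two non-target sites, in site order).")
  }
  S <- dist$scale
  S22 <- S[j, j, drop = FALSE]
  S12 <- S[i, j, drop = FALSE]
  w <- solve(S22, observed - dist$center[j])
  loc <- dist$center[i] + as.numeric(S12 %*% w)
  s11_2 <- S[i, i] - as.numeric(S12 %*% solve(S22, t(S12)))
  if (s11_2 <= 0) abort("Degenerate observed-block scale.")
  nu <- dist$dof
  if (is.finite(nu)) {
    d2 <- as.numeric((observed - dist$center[j]) %*% w)
    new_tdist1(nu + 2, loc, sqrt(s11_2 * (nu + d2) / (nu + 2)))
  } else {
    new_tdist1(Inf, loc, sqrt(s11_2))
  }
}

#' Analytic coverage of the ellipsoid diagnostic categories
#'
#' Probability that a T-score vector drawn from the zero-centered joint
#' model falls in each ellipsoid-rule category (see
#' [ellipsoid_classify()]).  Because the squared Mahalanobis radius of a
#' zero-centered trivariate normal vector is chi-squared with 3 df whatever
#' the correlations (and a scaled F(3, nu) quantity under the trivariate t),
#' the coverage is correlation-free:
#' `P(osteoporosis) = P(d >= r_op, sum < 0) = P(chi2_3 >= r_op^2) / 2`,
#' and similarly for the osteopenic shell between the two radii; the factor
#' 1/2 is the low-BMD half-space gate, which by elliptical symmetry carries
#' exactly half the mass of every shell.
#'
#' @param model Optional [correlation_model()]; accepted for interface
#'   symmetry and validated, but the result does not depend on it.
#' @param dof Degrees of freedom `nu` of the joint model (`Inf` = normal).
#' @param radii Length-2 vector `c(r_osteopenia, r_osteoporosis)`; must be
#'   increasing and positive.  Defaults to the WHO magnitudes `c(1, 2.5)`.
#' @return A tibble with columns `category` (diagnosis factor) and
#'   `probability`; the three probabilities sum to 1.
#' @examples
#' category_coverage()  # 0.0500, 0.3506, 0.5994 at nu = Inf
#' @export
category_coverage <- function(model = NULL, dof = Inf, radii = c(1, 2.5)) {
  if (!is.null(model)) model_matrix(model)
  check_number(dof, "dof", finite = FALSE)
  if (dof <= 0) abort("`dof` must be positive (or Inf).")
  if (!is.numeric(radii) || length(radii) != 2L || any(radii <= 0) ||
      radii[1] >= radii[2]) {
    abort("`radii` must be two positive radii c(r_osteopenia, r_osteoporosis) with r_osteopenia < r_osteoporosis.")
  }
  tail_p <- function(r) {
    if (is.finite(dof)) pf(r^2 / 3, 3, dof, lower.tail = FALSE)
    else pchisq(r^2, 3, lower.tail = FALSE)
  }
  p_op <- tail_p(radii[2]) / 2
  p_pen <- (tail_p(radii[1]) - tail_p(radii[2])) / 2
  tibble::tibble(
    category = as_diagnosis(c("normal", "osteopenia", "osteoporosis")),
    probability = c(1 - p_op - p_pen, p_pen, p_op)
  )
}
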