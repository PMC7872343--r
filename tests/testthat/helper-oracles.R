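# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: orthant probabilities come from the one-factor
# representation of the equicorrelated normal, densities from the textbook
# formulas written out directly, and matrix work from explicit solve().

# P(all three equicorrelated standard normals > a), via the one-factor
# representation X_i = sqrt(rho) Z + sqrt(1 - rho) E_i and quadrature.
orthant_gt <- function(a, rho) {
  if (rho == 0) return(pnorm(-a)^3)
  integrate(function(z) {
    dnorm(z) * pnorm((sqrt(rho) * z - a) / sqrt(1 - rho))^3
  }, -10, 10, rel.tol = 1e-10)$value
}

# P(all three equicorrelated standard normals in (lo, hi))
orthant_band <- function(lo, hi, rho) {
  if (rho == 0) return((pnorm(hi) - pnorm(lo))^3)
  integrate(function(z) {
    s <- sqrt(rho) * z
    (pnorm((s + hi) / sqrt(1 - rho)) - pnorm((s + lo) / sqrt(1 - rho)))^3 *
      dnorm(z)
  }, -10, 10, rel.tol = 1e-10)$value
}

# p-variate Student-t / normal density, textbook form with explicit solve()
dmvt_ref <- function(x, mu, S, nu) {
  p <- length(mu)
  d2 <- as.numeric(t(x - mu) %*% solve(S, x - mu))
  logdet <- as.numeric(determinant(S)$modulus)
  if (is.finite(nu)) {
    exp(lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(nu * pi) -
          0.5 * logdet - ((nu + p) / 2) * log1p(d2 / nu))
  } else {
    exp(-(p / 2) * log(2 * pi) - 0.5 * logdet - d2 / 2)
  }
}

# A random valid correlation model (positive definite by construction:
# correlations of a random full-rank 5 x 3 Gaussian matrix).
random_model <- function() {
  r <- cor(matrix(rnorm(18), ncol = 3))
  correlation_model(r[1, 2], r[1, 3], r[2, 3])
}

# The four worked example T-score triples quoted in the text
# (spine, femoral neck, total hip) and their lowest-T-score diagnoses.
worked_examples <- function() {
  tibble::tibble(
    patient_id = paste0("W", 1:4),
    t_l1l4 = c(-1.0, -1.1, -1.5, -1.5),
    t_fneck = c(-1.0, 1.5, 1.5, -1.4),
    t_thip = c(-1.0, 1.5, 1.5, -1.4),
    expected = c("normal", "osteopenia", "osteopenia", "osteopenia")
  )
}
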