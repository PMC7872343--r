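test_that("squared Mahalanobis distance matches closed forms and explicit inversion", {
  expect_equal(mahalanobis2(c(0, 0, 0), equicorrelation(0.4)), 0)
  expect_equal(mahalanobis2(c(-2.5, 0, 0), equicorrelation(0)), 6.25)
  # equicorrelated (1,1,1) direction: d^2 = sum^2-style closed form
  expect_equal(mahalanobis2(c(-1, -1, -1), equicorrelation(0.6)),
               3 / (1 + 2 * 0.6), tolerance = 1e-12)
  expect_equal(mahalanobis2(c(-2.5, -2.5, -2.5), equicorrelation(0.8)),
               18.75 / 2.6, tolerance = 1e-12)
  # random vectors vs explicit solve()
  set.seed(21)
  for (i in 1:10) {
    model <- random_model()
    x <- rnorm(3, sd = 2)
    expect_equal(mahalanobis2(x, model),
                 as.numeric(t(x) %*% solve(model$matrix, x)),
                 tolerance = 1e-10)
    expect_equal(mahalanobis2(x, model), mahalanobis2(-x, model))
  }
  expect_error(correlation_model(0.9, 0.9, -0.9), "positive definite")
})

test_that("joint density: mode value, unimodality, reference formula, normalisation", {
  dist_n <- tscore_distribution(equicorrelation(0))
  expect_equal(dtscore(c(0, 0, 0), dist_n), (2 * pi)^(-3 / 2),
               tolerance = 1e-12)

  set.seed(31)
  model <- equicorrelation(0.4)
  for (ref_n in c(6, 21, Inf)) {
    dist <- tscore_distribution(model, reference_n = ref_n)
    at_center <- dtscore(c(0, 0, 0), dist)
    pts <- matrix(rnorm(60, sd = 2), ncol = 3)
    expect_true(all(dtscore(pts, dist) <= at_center))
    # against the textbook density written out independently
    for (k in 1:5) {
      x <- rnorm(3, sd = 2)
      expect_equal(dtscore(x, dist),
                   dmvt_ref(x, dist$center, dist$scale, dist$dof),
                   tolerance = 1e-12)
    }
  }

  # trivariate t (nu = 5) integrates to 1: Simpson product rule on a box
  # wide enough that the truncated t mass is ~2e-5
  dist_t <- tscore_distribution(model, reference_n = 6)
  n_grid <- 141
  g <- seq(-20, 20, length.out = n_grid)
  h <- g[2] - g[1]
  w <- c(1, rep(c(4, 2), (n_grid - 3) / 2), 4, 1) * h / 3  # Simpson weights
  slice <- expand.grid(x = g, y = g)
  total <- 0
  for (k in seq_len(n_grid)) {
    dens <- dtscore(cbind(slice$x, slice$y, g[k]), dist_t)
    total <- total + w[k] * sum(dens * w[match(slice$x, g)] *
                                  w[match(slice$y, g)])
  }
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("marginals are univariate t/normal and agree with 2-D quadrature of the joint", {
  model <- equicorrelation(0.5)
  dist <- tscore_distribution(model)
  m1 <- marginal_distribution(dist, 1)
  expect_equal(dtdist1(0, m1), dnorm(0), tolerance = 1e-12)
  # symmetry: all three marginals identical under equicorrelation, zero center
  for (s in 2:3) {
    ms <- marginal_distribution(dist, s)
    expect_equal(ms$location, m1$location)
    expect_equal(ms$scale, m1$scale)
  }

  dist_t <- tscore_distribution(equicorrelation(0.4), reference_n = 7)
  marg <- marginal_distribution(dist_t, 2)
  expect_equal(marg$df, 6)
  expect_equal(marg$scale, sqrt(8 / 7), tolerance = 1e-12)
  for (x1 in c(-2.5, -1, 0, 0.7, 2)) {
    quad <- integrate(function(y) {
      vapply(y, function(yy) {
        integrate(function(z) dtscore(cbind(x1, yy, z), dist_t),
                  -Inf, Inf, rel.tol = 1e-9)$value
      }, numeric(1))
    }, -Inf, Inf, rel.tol = 1e-9)$value
    # integrating out sites 1 and 3 leaves the site-2 marginal; here the
    # equicorrelated zero-centered marginals coincide across sites
    expect_equal(dtdist1(x1, marg), quad, tolerance = 1e-5)
  }
})

test_that("conditionals: independence, normal closed form, joint factorisation", {
  # target uncorrelated with the observed pair: conditional == marginal
  dist0 <- tscore_distribution(correlation_model(0, 0, 0.6))
  cond0 <- conditional_distribution(dist0, 1, c(-2, 1))
  marg0 <- marginal_distribution(dist0, 1)
  expect_equal(cond0$location, marg0$location)
  expect_equal(cond0$scale, marg0$scale)

  # normal theory, equicorrelation rho, both observed equal x:
  # E[T1 | T2 = T3 = x] = 2 rho x / (1 + rho)
  for (rho in c(0.2, 0.6, 0.8)) {
    for (x in c(-2.5, -1, 0.5)) {
      cond <- conditional_distribution(tscore_distribution(equicorrelation(rho)),
                                       1, c(x, x))
      expect_equal(cond$location, 2 * rho * x / (1 + rho), tolerance = 1e-12)
      # cross-check by explicit linear solve
      R <- equicorrelation(rho)$matrix
      expect_equal(cond$location,
                   as.numeric(R[1, 2:3] %*% solve(R[2:3, 2:3], c(x, x))),
                   tolerance = 1e-12)
    }
  }

  # pointwise factorisation: joint = conditional * bivariate observed-block
  # marginal, for both finite and infinite dof
  set.seed(41)
  for (ref_n in c(8, Inf)) {
    model <- random_model()
    dist <- tscore_distribution(model, reference_n = ref_n)
    for (k in 1:10) {
      x <- rnorm(3, sd = 1.5)
      target <- sample(1:3, 1)
      obs_idx <- setdiff(1:3, target)
      cond <- conditional_distribution(dist, target, x[obs_idx])
      block <- dmvt_ref(x[obs_idx], dist$center[obs_idx],
                        dist$scale[obs_idx, obs_idx], dist$dof)
      joint <- dtscore(matrix(x, nrow = 1), dist)
      expect_equal(dtdist1(x[target], cond) * block, joint,
                   tolerance = 1e-8)
    }
  }
})

test_that("multivariate t converges to the normal as dof grows", {
  model <- equicorrelation(0.4)
  grid <- as.matrix(expand.grid(x = seq(-4, 4, by = 1),
                                y = seq(-4, 4, by = 1),
                                z = seq(-4, 4, by = 1)))
  normal <- dtscore(grid, tscore_distribution(model))
  sups <- vapply(c(11, 101, 1e4 + 1), function(m) {
    dist <- tscore_distribution(model, reference_n = m)
    max(abs(dtscore(grid, dist) - normal))
  }, numeric(1))
  expect_true(all(diff(sups) < 0))
  expect_lt(sups[3], 1e-3)
})

test_that("d^2 of zero-centered normal T-scores is chi-squared(3) for any model", {
  set.seed(51)
  for (rho in c(0, 0.65)) {
    model <- if (rho == 0) random_model() else equicorrelation(rho)
    cohort <- simulate_cohort(n = 1e5, correlation = model)
    d2 <- mahalanobis2(cohort, model)
    ks <- suppressWarnings(ks.test(d2, pchisq, df = 3))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("category coverage is analytic, correlation-free and sums to one", {
  cov <- category_coverage()
  expect_equal(sum(cov$probability), 1)
  expect_equal(cov$probability[cov$category == "osteoporosis"],
               pchisq(6.25, 3, lower.tail = FALSE) / 2, tolerance = 1e-12)
  expect_equal(cov$probability[cov$category == "osteopenia"],
               (pchisq(1, 3, lower.tail = FALSE) -
                  pchisq(6.25, 3, lower.tail = FALSE)) / 2, tolerance = 1e-12)
  # invariant to the correlation entries, to machine precision
  expect_identical(category_coverage(equicorrelation(0))$probability,
                   category_coverage(equicorrelation(0.8))$probability)
  expect_identical(category_coverage(correlation_model(0.66, 0.61, 0.75))$probability,
                   cov$probability)
  # finite dof: scaled-F law, cross-checked by simulation from the t model
  nu <- 9
  cov_t <- category_coverage(dof = nu)
  expect_equal(sum(cov_t$probability), 1)
  set.seed(61)
  n <- 2e5
  z <- matrix(rnorm(3 * n), ncol = 3)
  tdraw <- z / sqrt(rchisq(n, nu) / nu)  # spherical t: d^2 is rowSums^2
  d2 <- rowSums(tdraw^2)
  p_op_mc <- mean(d2 >= 6.25) / 2
  se <- sqrt(p_op_mc * (1 - p_op_mc) / n)
  expect_lt(abs(cov_t$probability[cov_t$category == "osteoporosis"] - p_op_mc),
            3 * se + 1e-4)
  expect_error(category_coverage(radii = c(2.5, 1)), "radii")
})
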