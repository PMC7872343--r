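test_that("lowest-T-score rule reproduces the worked examples and boundary conventions", {
  ex <- worked_examples()
  expect_equal(as.character(who_classify(ex)), ex$expected)
  # boundaries: osteoporosis inclusive at -2.5, normal inclusive at -1
  expect_equal(as.character(who_classify(c(-2.5, 0, 0))), "osteoporosis")
  expect_equal(as.character(who_classify(c(-1, 0, 0))), "normal")
  expect_equal(as.character(site_classify(c(-2.5, -2.4999, -1, -1.0000001, 0))),
               c("osteoporosis", "osteopenia", "normal", "osteopenia", "normal"))
  expect_error(who_classify(c(-1, NA, 0)), "finite")
  expect_error(who_classify(c(-1, 0)), "3 components")
})

test_that("diagnoses form an ordered scale", {
  d <- as_diagnosis(c("normal", "osteoporosis", "osteopenia"))
  expect_true(d[2] > d[3] && d[3] > d[1])
  expect_true(all((d >= "osteopenia") == c(FALSE, TRUE, TRUE)))
  expect_error(as_diagnosis("severe"), "must be one of")
})

test_that("congruence requires all three per-site diagnoses to agree", {
  out <- congruence(rbind(c(-2.6, -2.7, -3.0),
                          c(-2.6, -1.5, 0.0),
                          c(0.0, 0.5, 1.0)))
  expect_equal(out$congruent, c(TRUE, FALSE, TRUE))
  expect_equal(as.character(out$congruent_category),
               c("osteoporosis", NA, "normal"))
})

test_that("ellipsoid rule applies the radius thresholds behind the low-BMD gate", {
  expect_equal(as.character(ellipsoid_classify(c(-2.5, 0, 0), equicorrelation(0))),
               "osteoporosis")  # d = 2.5 exactly, inclusive
  expect_equal(as.character(ellipsoid_classify(c(0.5, 0.5, 0.5), equicorrelation(0.4))),
               "normal")        # high-BMD side fails the gate whatever d
  expect_equal(as.character(ellipsoid_classify(c(-1, -1, -1), equicorrelation(0.6))),
               "osteopenia")    # d^2 = 3/2.2 in (1, 6.25)
  expect_equal(as.character(ellipsoid_classify(c(-2.5, -2.5, -2.5), equicorrelation(0.8))),
               "osteoporosis")  # d^2 = 18.75/2.6 >= 6.25
  # boundary d = 1 exactly is normal (osteopenia strict at the inner radius)
  expect_equal(as.character(ellipsoid_classify(c(-1, 0, 0), equicorrelation(0))),
               "normal")
})

test_that("WHO severity is monotone in each component; ellipsoid severity in the radius", {
  set.seed(71)
  for (i in 1:50) {
    t <- rnorm(3, mean = -1, sd = 1.2)
    base <- who_classify(t)
    j <- sample(1:3, 1)
    worse <- t
    worse[j] <- worse[j] - runif(1, 0, 2)
    expect_true(who_classify(worse) >= base)
  }
  model <- equicorrelation(0.5)
  for (i in 1:25) {
    u <- rnorm(3)
    if (sum(u) >= 0) u <- -u - 1e-6
    lambda <- sort(runif(4, 0.1, 6))
    sev <- ellipsoid_classify(t(vapply(lambda, function(l) l * u, numeric(3))),
                              model)
    expect_true(all(diff(as.integer(sev)) >= 0))
  }
})

test_that("congruent-normal and WHO-normal are the same patients", {
  set.seed(81)
  for (rho in c(0, 0.4, 0.8)) {
    cls <- classify_cohort(simulate_cohort(n = 2000, rho = rho),
                           model = equicorrelation(rho))
    cong <- congruence(cls)
    expect_identical(
      sum(cong$congruent & cong$congruent_category == "normal", na.rm = TRUE),
      sum(cls$who_dx == "normal"))
    # and they are literally the same rows, not just the same count
    expect_identical(which(!is.na(cong$congruent_category) &
                             cong$congruent_category == "normal"),
                     which(cls$who_dx == "normal"))
  }
})

test_that("half of every exterior shell lies on the low-BMD side", {
  set.seed(91)
  n <- 4e4
  for (rho in c(0, 0.7)) {
    model <- equicorrelation(rho)
    cohort <- simulate_cohort(n = n, correlation = model)
    m <- as.matrix(cohort[c("t_l1l4", "t_fneck", "t_thip")])
    d2 <- mahalanobis2(m, model)
    for (r in c(1, 2.5)) {
      outside <- d2 >= r^2
      frac_low <- mean(rowSums(m[outside, ]) < 0)
      se <- sqrt(0.25 / sum(outside))
      expect_lt(abs(frac_low - 0.5), 4 * se)
    }
  }
})

test_that("classify_cohort appends diagnoses, d2 and congruence; counts are order-invariant", {
  cohort <- worked_examples()
  cls <- classify_cohort(cohort, model = equicorrelation(0.6))
  expect_named(cls, c(names(cohort), "who_dx", "ellipsoid_dx", "d2",
                      "congruent"))
  counts <- diagnosis_counts(cls)
  who <- counts[counts$rule == "who", ]
  expect_equal(who$n[who$category == "normal"], 1L)
  expect_equal(who$n[who$category == "osteopenia"], 3L)
  expect_equal(who$n[who$category == "osteoporosis"], 0L)
  expect_equal(sum(who$n), nrow(cohort))

  shuffled <- cohort[c(3, 1, 4, 2), ]
  counts2 <- diagnosis_counts(classify_cohort(shuffled,
                                              model = equicorrelation(0.6)))
  expect_equal(counts2, counts)

  # single-row cohort, both rules agree on a deep osteoporotic profile
  one <- classify_cohort(tibble::tibble(patient_id = "X", t_l1l4 = -3,
                                        t_fneck = -3, t_thip = -3),
                         model = equicorrelation(0.5))
  expect_equal(as.character(one$who_dx), "osteoporosis")
  expect_equal(as.character(one$ellipsoid_dx), "osteoporosis")

  # empty cohort: empty summary, schema intact
  empty <- classify_cohort(worked_examples()[0, ], model = equicorrelation(0.5))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("who_dx", "ellipsoid_dx", "d2", "congruent") %in%
                    names(empty)))
})

test_that("the default correlation model is the cohort's own Pearson correlations", {
  set.seed(101)
  cohort <- simulate_cohort(n = 500, correlation = correlation_model(0.6, 0.5, 0.7))
  model <- cohort_correlation(cohort)
  m <- as.matrix(cohort[c("t_l1l4", "t_fneck", "t_thip")])
  expect_equal(model$rho12, cor(m[, 1], m[, 2]), tolerance = 1e-12)
  cls_default <- classify_cohort(cohort)
  cls_explicit <- classify_cohort(cohort, model = model)
  expect_identical(cls_default$ellipsoid_dx, cls_explicit$ellipsoid_dx)
})

test_that("WHO osteoporosis is not always contained in ellipsoid osteoporosis", {
  # a single very low site with two high sites passes the WHO rule but can
  # fail the low-BMD gate; the disagreement is surfaced, not forced away
  t <- c(-2.5, 2, 2)
  expect_equal(as.character(who_classify(t)), "osteoporosis")
  expect_equal(as.character(ellipsoid_classify(t, equicorrelation(0))), "normal")
})
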