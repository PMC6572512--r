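test_that("Cockcroft-Gault creatinine clearance matches hand evaluation", {
  m <- patients(age = 40, sex = "male", weight = 72, scr = 1)
  f <- patients(age = 40, sex = "female", weight = 72, scr = 1)
  expect_equal(compute_clcr(m)$clcr, 100)
  expect_equal(compute_clcr(f)$clcr, 85)

  # explicit clcr overrides the formula
  o <- patients(age = 40, sex = "male", weight = 72, scr = 1, clcr = 55)
  expect_equal(compute_clcr(o)$clcr, 55)

  # CLCR -> 0 as serum creatinine grows
  hi <- patients(age = 40, sex = "male", weight = 72, scr = 1e6)
  expect_lt(compute_clcr(hi)$clcr, 1e-3)
})

test_that("missing covariates raise an explicit error, never a default", {
  expect_error(patients(age = 40, sex = "male", weight = 72),
               "insufficient covariates")
  p <- patients(age = 40, sex = "male", weight = 72, clcr = 90)
  p$clcr <- NA_real_  # strip after construction to hit the compute path
  p$scr <- NA_real_
  expect_error(compute_clcr(p), "insufficient covariates")
  expect_error(patients(age = 40, sex = "male", weight = 70, scr = 1,
                        hd = TRUE, crrt = TRUE), "mutually exclusive")
})

test_that("covariate model reproduces the published typical values", {
  expect_equal(individual_params(pat_ref, pop)$cl, 2.82)
  expect_equal(individual_params(pat_ref, pop)$v2, 75.4)

  crrt <- patients(age = 60, sex = "male", weight = 60, crrt = TRUE)
  hd <- patients(age = 60, sex = "male", weight = 60, hd = TRUE)
  expect_equal(individual_params(crrt, pop)$cl, 0.716)
  expect_equal(individual_params(hd, pop)$cl, 0.334)

  # power function at doubled CLCR
  p144 <- patients(age = 60, sex = "male", weight = 60, clcr = 144)
  expect_equal(individual_params(p144, pop)$cl, 2.82 * 2^0.836)
})

test_that("random effects act multiplicatively and only on CL and V2", {
  eta <- tibble::tibble(eta_cl = 0.7, eta_v2 = -0.4)
  ip0 <- individual_params(pat_g1, pop)
  ip1 <- individual_params(pat_g1, pop, eta)
  expect_equal(ip1$cl, ip0$cl * exp(0.7))
  expect_equal(ip1$v2, ip0$v2 * exp(-0.4))
  expect_equal(ip1$v1, pop$v1)
  expect_equal(ip1$q, pop$q)

  # homogeneity of degree 1 in exp(eta_cl)
  k <- 3
  ipk <- individual_params(pat_g1, pop,
                           tibble::tibble(eta_cl = 0.7 + log(k), eta_v2 = -0.4))
  expect_equal(ipk$cl, ip1$cl * k)
})

test_that("CL is increasing in CLCR and RRT regimes ignore creatinine", {
  clcrs <- c(10, 40, 72, 100, 200)
  cls <- vapply(clcrs, function(x)
    individual_params(patients(age = 60, sex = "male", weight = 60, clcr = x),
                      pop)$cl, numeric(1))
  expect_true(all(diff(cls) > 0))

  hd1 <- patients(age = 60, sex = "male", weight = 60, scr = 1, hd = TRUE)
  hd2 <- patients(age = 60, sex = "male", weight = 60, scr = 9, hd = TRUE)
  expect_identical(individual_params(hd1, pop),
                   individual_params(hd2, pop))
  expect_error(
    individual_params(dplyr::mutate(pat_g1, clcr = -5), pop), "clcr|CLCR")
})

test_that("CV%% <-> omega^2 transforms are exact inverses", {
  expect_equal(cv_to_omega2(0), 0)
  expect_equal(cv_to_omega2(99.2), log(1 + 0.992^2))
  expect_equal(cv_to_omega2(99.2), 0.6852, tolerance = 1e-4)
  for (x in c(10, 49.2, 200))
    expect_equal(omega2_to_cv(cv_to_omega2(x)), x, tolerance = 1e-12)
  for (w in c(0.01, 0.5, 2))
    expect_equal(cv_to_omega2(omega2_to_cv(w)), w, tolerance = 1e-12)
  expect_error(cv_to_omega2(-1))
  expect_error(omega2_to_cv(-0.1))
})

test_that("parameter files round-trip and validate", {
  p <- default_params()
  expect_equal(p$theta1, 2.82)
  expect_equal(p$omega2_cl, cv_to_omega2(99.2))
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, tf)
  p2 <- read_params(tf)
  expect_equal(unclass(p2), unclass(p))
  expect_error(vanco_params(theta1 = -1), "theta1")
  expect_error(vanco_params(sigma_add = 0, sigma_prop = 0), "degenerate")
})
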