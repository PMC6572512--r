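test_that("hybrid constants satisfy their defining identities", {
  mc <- micro_constants(tibble::tibble(cl = 2.82, v1 = 31.8, q = 11.7,
                                       v2 = 75.4))
  expect_equal(mc$alpha * mc$beta, (2.82 / 31.8) * (11.7 / 75.4),
               tolerance = 1e-10)
  expect_gt(mc$alpha, mc$beta)
  expect_gt(mc$beta, 0)

  # Q = 0 decouples the peripheral compartment
  mc0 <- micro_constants(tibble::tibble(cl = 3, v1 = 30, q = 0, v2 = 70))
  expect_equal(mc0$alpha, 3 / 30)
  expect_equal(mc0$beta, 0)

  withr::with_seed(11, {
    for (i in 1:25) {
      ip <- tibble::tibble(cl = runif(1, 0.1, 10), v1 = runif(1, 5, 80),
                           q = runif(1, 0.01, 30), v2 = runif(1, 10, 200))
      m <- micro_constants(ip)
      expect_equal(m$alpha + m$beta, m$k10 + m$k12 + m$k21, tolerance = 1e-10)
      expect_equal(m$alpha * m$beta, m$k10 * m$k21, tolerance = 1e-10)
    }
  })
})

test_that("closed-form prediction is linear in dose and superposable", {
  tt <- c(0, 0.5, 1, 3, 12, 24.5, 100, 167)
  c1 <- predict_conc(ip_g1, reg_std, tt)$conc
  reg2 <- dose_events(reg_std$start_time, 2 * reg_std$amount,
                      reg_std$duration)
  expect_equal(predict_conc(ip_g1, reg2, tt)$conc, 2 * c1)

  # superposition: split the schedule into odd/even doses
  a <- reg_std[seq(1, 7, by = 2), ]; b <- reg_std[seq(2, 7, by = 2), ]
  ca <- predict_conc(ip_g1, dose_events(a$start_time, a$amount, a$duration), tt)$conc
  cb <- predict_conc(ip_g1, dose_events(b$start_time, b$amount, b$duration), tt)$conc
  expect_equal(ca + cb, c1)

  expect_equal(nrow(predict_conc(ip_g1, reg_std, numeric(0))), 0L)
  expect_equal(predict_conc(ip_g1, dose_events(10, 1000, 1), c(0, 5, 9.9))$conc,
               c(0, 0, 0))
})

test_that("closed form agrees with the ODE oracle to 1e-6", {
  withr::with_seed(21, {
    for (r in 1:5) {
      reg <- dose_events(start_time = cumsum(runif(4, 4, 30)) - 4,
                         amount = runif(4, 250, 2000),
                         duration = runif(4, 0.5, 3))
      ip <- tibble::tibble(cl = runif(1, 0.3, 8), v1 = runif(1, 10, 60),
                           q = runif(1, 0, 25), v2 = runif(1, 20, 150))
      tt <- sort(runif(50, 0, max(reg$start_time) + 60))
      cf <- predict_conc(ip, reg, tt)$conc
      od <- ode_conc(ip, reg, tt)$conc
      expect_lt(max(abs(cf - od) / pmax(od, 1e-8)), 1e-6)
    }
  })
})

test_that("profile converges to the one-compartment solution as Q -> 0", {
  reg <- dose_events(0, 1000, 1)
  tt <- c(0.25, 0.5, 1, 2, 6, 12)
  cl <- 3; v1 <- 30
  k <- cl / v1
  one_cpt <- ifelse(tt <= 1,
                    1000 / 1 / cl * (1 - exp(-k * tt)),
                    1000 / 1 / cl * (1 - exp(-k)) * exp(-k * (tt - 1)))
  exact0 <- predict_conc(tibble::tibble(cl = cl, v1 = v1, q = 0, v2 = 70),
                         reg, tt)$conc
  expect_equal(exact0, one_cpt, tolerance = 1e-12)
  small_q <- predict_conc(tibble::tibble(cl = cl, v1 = v1, q = 1e-7, v2 = 70),
                          reg, tt)$conc
  expect_equal(small_q, one_cpt, tolerance = 1e-5)
})

test_that("analytic AUC obeys the clearance identity", {
  ip <- tibble::tibble(cl = 3.71, v1 = 31.8, q = 11.7, v2 = 75.4)
  expect_equal(auc_window(ip, dose_events(0, 1000, 1), 0, 5000),
               1000 / 3.71, tolerance = 1e-8)
  # ODE-based cross-check of a finite window
  f <- function(t) predict_conc(ip, reg_std, t)$conc
  num <- stats::integrate(Vectorize(f), 144, 168, subdivisions = 500,
                          rel.tol = 1e-9)$value
  expect_equal(auc_window(ip, reg_std, 144, 168), num, tolerance = 1e-6)
})

test_that("steady-state summary anchors peak, trough and AUC24 correctly", {
  m <- steady_state_metrics(ip_g1, reg_std)
  expect_equal(m$cpeak, predict_conc(ip_g1, reg_std, 145)$conc)
  expect_equal(m$ctrough, predict_conc(ip_g1, reg_std, 168)$conc)
  expect_lt(m$ctrough, m$cpeak)
  # at (approached) steady state, AUC24 ~ daily dose / CL within 2%
  expect_equal(m$auc24, 1000 / ip_g1$cl, tolerance = 0.02)
  expect_error(steady_state_metrics(ip_g1, dose_events(0, 1000, 1)),
               "single dose")
})

test_that("a subject with higher clearance has a lower trough at every cycle end", {
  hi <- dplyr::mutate(ip_g1, cl = cl * 2)
  ends <- reg_std$start_time[-1]
  expect_true(all(predict_conc(hi, reg_std, ends)$conc <
                  predict_conc(ip_g1, reg_std, ends)$conc))
})
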