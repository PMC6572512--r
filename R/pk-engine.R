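#' Hybrid rate constants of the two-compartment model
#'
#' Reparameterizes clearance/volume parameters into micro rate constants
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` and the hybrid disposition
#' constants `alpha`, `beta` (1/h), the roots of
#' \eqn{\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0}
#' with \eqn{\alpha \ge \beta \ge 0}. The discriminant is evaluated as
#' \eqn{(k_{10}+k_{12}-k_{21})^2 + 4 k_{12} k_{21}} and \eqn{\beta} as
#' \eqn{k_{10}k_{21}/\alpha}, both exact rearrangements that avoid
#' catastrophic cancellation when the roots are close. When `Q = 0` the
#' peripheral compartment decouples: `beta = 0` and the model degenerates to
#' one-compartment elimination at rate `alpha = k10`.
#'
#' @param ip Individual parameter table with columns `cl`, `v1`, `q`, `v2`
#'   (as from [individual_params()]).
#' @return A tibble with columns `k10`, `k12`, `k21`, `alpha`, `beta`.
#' @examples
#' micro_constants(tibble::tibble(cl = 2.82, v1 = 31.8, q = 11.7, v2 = 75.4))
#' @export
micro_constants <- function(ip) {
  check_ip(ip)
  k10 <- ip$cl / ip$v1
  k12 <- ip$q / ip$v1
  k21 <- ip$q / ip$v2
  disc <- sqrt((k10 + k12 - k21)^2 + 4 * k12 * k21)
  alpha <- (k10 + k12 + k21 + disc) / 2
  beta <- k10 * k21 / alpha
  tibble::tibble(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

check_ip <- function(ip) {
  miss <- setdiff(c("cl", "v1", "q", "v2"), names(ip))
  if (length(miss))
    abort(paste0("individual parameters need columns: ",
                 paste(miss, collapse = ", ")))
  if (any(ip$cl <= 0) || any(ip$v1 <= 0) || any(ip$v2 <= 0))
    abort("`cl`, `v1`, `v2` must be > 0")
  if (any(ip$q < 0)) abort("`q` must be >= 0")
  invisible(ip)
}

# (1 - exp(-lam * tau)) / lam for an n-vector lam and m-vector tau,
# with the lam -> 0 limit tau. Returns n x m.
.ginf <- function(lam, tau) {
  g <- -expm1(-outer(lam, tau)) / lam
  z <- lam == 0
  if (any(z)) g[z, ] <- matrix(tau, sum(z), length(tau), byrow = TRUE)
  g
}

# Central concentration (mg/L), n subjects x m times, by closed-form
# superposition of zero-order infusion responses. Exact for the linear model.
.conc_matrix <- function(cl, v1, q, v2, reg, times) {
  n <- length(cl)
  m <- length(times)
  out <- matrix(0, n, m)
  if (m == 0L || n == 0L) return(out)
  mc <- micro_constants(tibble::tibble(cl = cl, v1 = v1, q = q, v2 = v2))
  ab <- mc$alpha - mc$beta
  A <- (mc$alpha - mc$k21) / ab    # ab > 0 whenever k10 > 0
  B <- (mc$k21 - mc$beta) / ab
  for (d in seq_len(nrow(reg))) {
    tau <- times - reg$start_time[d]
    if (all(tau <= 0)) next
    Tinf <- reg$duration[d]
    rate <- reg$amount[d] / Tinf
    te <- pmin(pmax(tau, 0), Tinf)   # elapsed infusion time
    tp <- pmax(tau - Tinf, 0)        # time since end of infusion
    term <- A * (.ginf(mc$alpha, te) * exp(-outer(mc$alpha, tp))) +
            B * (.ginf(mc$beta,  te) * exp(-outer(mc$beta,  tp)))
    out <- out + (rate / v1) * term
  }
  out[out < 0] <- 0  # clip exact-arithmetic dust at t = dose start
  out
}

# Cumulative integral of each dose's concentration from its start to time t,
# summed over doses: n subjects x length(at) windows are handled by the
# caller via differences. Returns n x m matrix of AUC(0 -> times).
.cumauc_matrix <- function(cl, v1, q, v2, reg, times) {
  n <- length(cl)
  m <- length(times)
  out <- matrix(0, n, m)
  if (m == 0L || n == 0L) return(out)
  mc <- micro_constants(tibble::tibble(cl = cl, v1 = v1, q = q, v2 = v2))
  ab <- mc$alpha - mc$beta
  A <- (mc$alpha - mc$k21) / ab
  B <- (mc$k21 - mc$beta) / ab
  H <- function(lam, te, tp) {
    # int_0^tau of the unit-rate single-dose response for one exponential
    g_te <- .ginf(lam, te)
    te_m <- matrix(te, length(lam), length(te), byrow = TRUE)
    during <- (te_m - g_te) / lam     # rows with lam == 0 fixed below
    z <- lam == 0
    if (any(z)) during[z, ] <- matrix(te^2 / 2, sum(z), length(te), byrow = TRUE)
    during + g_te * .ginf(lam, tp)
  }
  for (d in seq_len(nrow(reg))) {
    tau <- times - reg$start_time[d]
    if (all(tau <= 0)) next
    Tinf <- reg$duration[d]
    rate <- reg$amount[d] / Tinf
    te <- pmin(pmax(tau, 0), Tinf)
    tp <- pmax(tau - Tinf, 0)
    out <- out + (rate / v1) *
      (A * H(mc$alpha, te, tp) + B * H(mc$beta, te, tp))
  }
  out
}

#' Predict plasma concentrations under a dosing history
#'
#' Central-compartment vancomycin concentration from the closed-form
#' zero-order-infusion solution of the two-compartment model, summed over all
#' doses by linear superposition (during-infusion and post-infusion branches
#' per dose). Exact for the linear model: no discretization error. Times
#' before the first dose return 0.
#'
#' @param ip Individual parameter table (`cl`, `v1`, `q`, `v2`); one or more
#'   rows.
#' @param reg A [regimen()].
#' @param times Evaluation times, h (>= 0).
#' @return A tibble with columns `time` (h) and `conc` (mg/L), plus a
#'   `subject` column when `ip` has several rows.
#' @examples
#' ip <- individual_params(patients(age = 60, sex = "male", weight = 60,
#'                                  clcr = 100), vanco_params())
#' predict_conc(ip, regimen(1000, 24, 7, 1), times = c(1, 24, 145, 168))
#' @export
predict_conc <- function(ip, reg, times) {
  check_ip(ip)
  reg <- as_regimen(reg)
  times <- as.numeric(times)
  if (any(times < 0)) abort("`times` must be >= 0")
  cm <- .conc_matrix(ip$cl, ip$v1, ip$q, ip$v2, reg, times)
  if (nrow(ip) == 1L) {
    tibble::tibble(time = times, conc = cm[1L, ])
  } else {
    tidyr::expand_grid(subject = seq_len(nrow(ip)), time = times) |>
      dplyr::mutate(conc = as.vector(t(cm)))
  }
}

#' ODE oracle for the two-compartment infusion model
#'
#' Independent numerical check of [predict_conc()]: integrates the amount
#' equations
#' \deqn{dA_1/dt = in(t) - (k_{10}+k_{12}) A_1 + k_{21} A_2, \qquad
#'       dA_2/dt = k_{12} A_1 - k_{21} A_2}
#' with \eqn{in(t) = amount/duration} during each infusion, piecewise across
#' infusion start/stop breakpoints with `deSolve::lsoda` at tight tolerance,
#' and returns \eqn{A_1/V_1}. Used by the test suite to validate the closed
#' form; the closed form is the production path.
#'
#' @inheritParams predict_conc
#' @param rtol,atol Integration tolerances passed to `deSolve::lsoda`.
#' @return A tibble with columns `time` and `conc` (single subject).
#' @export
ode_conc <- function(ip, reg, times, rtol = 1e-11, atol = 1e-11) {
  check_ip(ip)
  if (nrow(ip) != 1L) abort("`ode_conc()` integrates one subject at a time")
  reg <- as_regimen(reg)
  times <- as.numeric(times)
  if (any(times < 0)) abort("`times` must be >= 0")
  k10 <- ip$cl / ip$v1; k12 <- ip$q / ip$v1; k21 <- ip$q / ip$v2

  tq <- sort(unique(times))
  brk <- sort(unique(c(0, reg$start_time, reg$start_time + reg$duration, tq)))
  rate_at <- function(t) {
    sum(reg$amount / reg$duration *
          (reg$start_time <= t & t < reg$start_time + reg$duration))
  }
  derivs <- function(t, y, parms) {
    list(c(parms$rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  y <- c(A1 = 0, A2 = 0)
  conc_q <- numeric(length(tq))  # tq[1] is always a segment start (conc 0 there)
  for (i in seq_len(length(brk) - 1L)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    seg_t <- unique(c(t0, tq[tq > t0 & tq <= t1], t1))
    sol <- deSolve::lsoda(y, seg_t, derivs,
                          parms = list(rate = rate_at((t0 + t1) / 2)),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      abort("ODE integration failed in `ode_conc()`")
    hit <- which(tq > t0 & tq <= t1)
    if (length(hit))
      conc_q[hit] <- sol[match(tq[hit], seg_t), 2L] / ip$v1
    y <- setNames(as.numeric(sol[nrow(sol), c(2L, 3L)]), c("A1", "A2"))
  }
  tibble::tibble(time = times, conc = conc_q[match(times, tq)])
}

#' Area under the concentration curve over a time window
#'
#' Analytic integral of the closed-form concentration curve between `from`
#' and `to` (h), per subject. No trapezoidal error.
#'
#' @inheritParams predict_conc
#' @param from,to Window bounds, h (`0 <= from < to`).
#' @return Numeric vector of AUC values, mg·h/L, one per `ip` row.
#' @export
auc_window <- function(ip, reg, from, to) {
  check_ip(ip)
  reg <- as_regimen(reg)
  if (from < 0 || to <= from) abort("need 0 <= from < to")
  cum <- .cumauc_matrix(ip$cl, ip$v1, ip$q, ip$v2, reg, c(from, to))
  cum[, 2L] - cum[, 1L]
}

#' Steady-state exposure summary for a repeating regimen
#'
#' Clinical TDM anchors on the final dosing interval of the regimen:
#' `cpeak` is the concentration at the end of the last infusion, `ctrough`
#' the concentration at the end of the last dosing interval (immediately
#' before the next scheduled dose, the interval being inferred from the last
#' two dose times), and `auc24` the analytic integral over the final 24 h.
#'
#' @inheritParams predict_conc
#' @return A tibble with columns `cpeak` (mg/L), `ctrough` (mg/L), `auc24`
#'   (mg·h/L), one row per `ip` row.
#' @examples
#' ip <- individual_params(patients(age = 60, sex = "male", weight = 60,
#'                                  clcr = 100), vanco_params())
#' steady_state_metrics(ip, regimen(1000, 24, 7, 1))
#' @export
steady_state_metrics <- function(ip, reg) {
  check_ip(ip)
  reg <- as_regimen(reg)
  tau <- last_interval(reg)
  t_last <- reg$start_time[nrow(reg)]
  t_peak <- t_last + reg$duration[nrow(reg)]
  t_trough <- t_last + tau
  cm <- .conc_matrix(ip$cl, ip$v1, ip$q, ip$v2, reg, c(t_peak, t_trough))
  tibble::tibble(
    cpeak = cm[, 1L],
    ctrough = cm[, 2L],
    auc24 = auc_window(ip, reg, max(t_trough - 24, 0), t_trough)
  )
}
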