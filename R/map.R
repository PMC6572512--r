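#' Combined residual-error variance
#'
#' Variance of the measurement error around a model-predicted concentration
#' `f` under the combined (additive + proportional) residual model:
#' \eqn{Var = \sigma_{add}^2 + (\sigma_{prop} f)^2}, in (mg/L)^2. Both sigma
#' terms are standard deviations as stored in [vanco_params()].
#'
#' @param params A [vanco_params()] object.
#' @param f Predicted concentration(s), mg/L (>= 0).
#' @return Residual variance(s), (mg/L)^2.
#' @examples
#' residual_variance(vanco_params(), f = 20)
#' @export
residual_variance <- function(params, f) {
  stopifnot(inherits(params, "vanco_params"))
  if (any(f < 0)) abort("`f` must be >= 0")
  v <- params$sigma_add^2 + (params$sigma_prop * f)^2
  if (any(v <= 0))
    abort("degenerate residual variance: prediction 0 with no additive error")
  v
}

#' MAP objective function (-2 log posterior, up to a constant)
#'
#' The empirical-Bayes objective minimized to estimate a patient's random
#' effects from observed concentrations:
#' \deqn{O(\eta) = \sum_j \left[\ln \sigma_j^2 +
#'   \frac{(y_j - F_j)^2}{\sigma_j^2}\right] + \eta^T \Omega^{-1} \eta,}
#' where \eqn{F_j} is the model prediction at observation time `j` under
#' `eta`, \eqn{\sigma_j^2} the combined residual variance at \eqn{F_j}, and
#' \eqn{\Omega = diag(\omega^2_{CL}, \omega^2_{V2})} the BSV covariance.
#' Natural logs throughout; the constant \eqn{\ln 2\pi} terms are omitted as
#' they do not affect the argmin.
#'
#' @param eta Numeric length-2 vector `c(eta_cl, eta_v2)` (log scale).
#' @param obs Tibble of observations with columns `time` (h) and `conc`
#'   (mg/L); may have zero rows.
#' @param patient Single-row patient table ([patients()]).
#' @param reg A [regimen()].
#' @param params A [vanco_params()] object.
#' @param omega Optional 2x2 BSV covariance matrix overriding the diagonal
#'   default (forward compatibility with correlated random effects).
#' @return The objective value (scalar).
#' @export
map_objective <- function(eta, obs, patient, reg, params, omega = NULL) {
  stopifnot(inherits(params, "vanco_params"))
  if (length(eta) != 2L || any(!is.finite(eta)))
    abort("`eta` must be two finite values (eta_cl, eta_v2)")
  om <- omega %||% diag(c(params$omega2_cl, params$omega2_v2))
  if (any(diag(om) <= 0))
    abort("BSV covariance must be positive definite (zero omega term found)")
  prior <- drop(t(eta) %*% solve(om) %*% eta)
  if (nrow(obs) == 0L) return(prior)
  ip <- individual_params(patient, params,
                          tibble::tibble(eta_cl = eta[1L], eta_v2 = eta[2L]))
  f <- predict_conc(ip, reg, obs$time)$conc
  s2 <- residual_variance(params, f)
  sum(log(s2) + (obs$conc - f)^2 / s2) + prior
}

#' MAP empirical-Bayes estimation of individual random effects
#'
#' Estimates a patient's `(eta_cl, eta_v2)` by minimizing [map_objective()]
#' over the observed concentrations, yielding individualized CL and V2 for
#' Bayesian-feedback dose adjustment. Observations above the outlier ceiling
#' (default 100 mg/L) are excluded before fitting and counted. With no
#' usable observations the prior mode `eta = (0, 0)` is returned (with a
#' warning if observations were all excluded as outliers).
#'
#' Optimization runs a multi-start scheme (eta = 0 plus one-SD perturbations
#' along each axis), each start using Nelder-Mead followed by a BFGS polish;
#' the best objective wins.
#'
#' @inheritParams map_objective
#' @param obs Observation tibble (`time`, `conc`).
#' @param outlier_ceiling Concentration ceiling, mg/L; strictly greater
#'   values are excluded.
#' @param reltol Relative convergence tolerance on the objective.
#' @return An object of class `vanco_map`: list with `eta` (named length-2),
#'   `objective`, `individual` (tibble `cl`, `v1`, `q`, `v2`), `converged`,
#'   `n_obs_used`, `n_excluded`, plus the inputs. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' pop <- vanco_params()
#' pat <- patients(age = 60, sex = "male", weight = 60, clcr = 100)
#' reg <- regimen(1000, 24, 7, 1)
#' obs <- tibble::tibble(time = c(25.5, 47.5), conc = c(22, 11))
#' fit <- map_fit(obs, pat, reg, pop)
#' tidy(fit)
#' @export
map_fit <- function(obs, patient, reg, params, omega = NULL,
                    outlier_ceiling = 100, reltol = 1e-10) {
  stopifnot(inherits(params, "vanco_params"))
  if (nrow(patient) != 1L) abort("`map_fit()` fits one patient at a time")
  reg <- as_regimen(reg)
  if (!all(c("time", "conc") %in% names(obs)))
    abort("`obs` must have columns `time` and `conc`")
  if (any(obs$time < 0)) abort("observation times must be >= 0")
  if (any(obs$conc <= 0)) abort("observed concentrations must be > 0")

  keep <- obs$conc <= outlier_ceiling
  n_excluded <- sum(!keep)
  obs_used <- obs[keep, , drop = FALSE]
  if (nrow(obs) > 0L && nrow(obs_used) == 0L)
    warn("all observations exceed the outlier ceiling; returning the prior mode (eta = 0)")

  fn <- function(e) map_objective(e, obs_used, patient, reg, params, omega)

  if (nrow(obs_used) == 0L) {
    eta <- c(eta_cl = 0, eta_v2 = 0)
    best <- list(par = c(0, 0), value = fn(c(0, 0)), convergence = 0L)
  } else {
    sd_cl <- sqrt(params$omega2_cl); sd_v2 <- sqrt(params$omega2_v2)
    starts <- list(c(0, 0), c(sd_cl, 0), c(-sd_cl, 0), c(0, sd_v2), c(0, -sd_v2))
    runs <- lapply(starts, function(s) {
      nm <- optim(s, fn, method = "Nelder-Mead",
                  control = list(reltol = reltol, maxit = 2000))
      bf <- tryCatch(
        optim(nm$par, fn, method = "BFGS",
              control = list(reltol = reltol, maxit = 500)),
        error = function(e) nm)
      if (bf$value <= nm$value) bf else nm
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    eta <- c(eta_cl = best$par[1L], eta_v2 = best$par[2L])
  }

  ind <- individual_params(patient, params,
                           tibble::tibble(eta_cl = eta[[1L]], eta_v2 = eta[[2L]]))
  structure(list(
    eta = eta,
    objective = best$value,
    individual = ind[, c("cl", "v1", "q", "v2")],
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    n_obs_used = nrow(obs_used),
    n_excluded = n_excluded,
    obs = obs, patient = patient, regimen = reg, params = params
  ), class = "vanco_map")
}

#' @export
print.vanco_map <- function(x, ...) {
  cat("<vanco_map> MAP empirical-Bayes fit\n")
  cat(sprintf("  eta_cl = %+.4f, eta_v2 = %+.4f  (objective %.4f, %s)\n",
              x$eta[["eta_cl"]], x$eta[["eta_v2"]], x$objective,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  CL = %.3g L/h, V1 = %.3g L, Q = %.3g L/h, V2 = %.3g L\n",
              x$individual$cl, x$individual$v1, x$individual$q,
              x$individual$v2))
  cat(sprintf("  %d observation(s) used, %d excluded as outliers\n",
              x$n_obs_used, x$n_excluded))
  invisible(x)
}

#' @rdname map_fit
#' @param x A `vanco_map` object.
#' @param ... Unused.
#' @export
tidy.vanco_map <- function(x, ...) {
  tibble::tibble(
    term = c("eta_cl", "eta_v2", "cl", "v1", "q", "v2"),
    estimate = c(x$eta[["eta_cl"]], x$eta[["eta_v2"]],
                 x$individual$cl, x$individual$v1, x$individual$q,
                 x$individual$v2),
    unit = c("log", "log", "L/h", "L", "L/h", "L")
  )
}

#' @rdname map_fit
#' @export
glance.vanco_map <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_obs_used = x$n_obs_used, n_excluded = x$n_excluded)
}
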