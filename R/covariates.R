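#' Individual pharmacokinetic parameters from covariates and random effects
#'
#' Applies the covariate model and the log-normal between-subject variability
#' to produce per-patient structural parameters:
#' \deqn{CL = CL_{typ} \, e^{\eta_{CL}}, \qquad
#'       V_2 = \theta_3 (WT/60) \, e^{\eta_{V2}},}
#' where the typical clearance is `cl_crrt` under CRRT, `cl_hd` under HD, and
#' \eqn{\theta_1 (CLCR/72)^{\theta_2}} otherwise. `V1` and `Q` carry no
#' random effects and are the population values.
#'
#' For non-RRT rows, a missing `clcr` is resolved by [compute_clcr()].
#'
#' @param p Patient table ([patients()]); one row per subject.
#' @param params A [vanco_params()] object.
#' @param eta Data frame with columns `eta_cl`, `eta_v2` (log scale), one row
#'   per patient or a single row recycled. Default: all zero (typical
#'   subject).
#' @return A tibble with columns `cl`, `v1`, `q`, `v2` (L/h, L, L/h, L), one
#'   row per patient, alongside `eta_cl` and `eta_v2`.
#' @examples
#' individual_params(patients(age = 60, sex = "male", weight = 60, clcr = 72),
#'                   vanco_params())
#' @export
individual_params <- function(p, params, eta = NULL) {
  stopifnot(inherits(params, "vanco_params"))
  validate_patients(p)
  n <- nrow(p)
  if (is.null(eta)) eta <- tibble::tibble(eta_cl = 0, eta_v2 = 0)
  if (!all(c("eta_cl", "eta_v2") %in% names(eta)))
    abort("`eta` must have columns `eta_cl` and `eta_v2`")
  if (nrow(eta) == 1L && n > 1L) eta <- eta[rep(1L, n), ]
  if (n == 1L && nrow(eta) > 1L) {  # one template patient, many eta draws
    p <- p[rep(1L, nrow(eta)), ]
    n <- nrow(eta)
  }
  if (nrow(eta) != n) abort("`eta` must have 1 row or one row per patient")
  if (any(!is.finite(eta$eta_cl)) || any(!is.finite(eta$eta_v2)))
    abort("`eta` values must be finite")

  need_clcr <- !p$hd & !p$crrt & is.na(p$clcr)
  if (any(need_clcr)) p <- compute_clcr(p)
  if (any(!p$hd & !p$crrt & p$clcr <= 0))
    abort("CLCR must be > 0 for patients not on HD/CRRT")

  cl_typ <- ifelse(p$crrt, params$cl_crrt,
            ifelse(p$hd, params$cl_hd,
                   params$theta1 * (p$clcr / params$ref_clcr)^params$theta2))
  tibble::tibble(
    cl = cl_typ * exp(eta$eta_cl),
    v1 = rep(params$v1, n),
    q  = rep(params$q, n),
    v2 = params$theta3 * (p$weight / params$ref_wt) * exp(eta$eta_v2),
    eta_cl = eta$eta_cl,
    eta_v2 = eta$eta_v2
  )
}
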