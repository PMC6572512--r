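#' Population pharmacokinetic parameters
#'
#' Constructs the set of population parameters that drives every computation
#' in the package: the structural/covariate model of vancomycin disposition
#' (two compartments, first-order elimination, zero-order IV infusion input),
#' the between-subject variability (BSV) terms, and the combined residual
#' error model.
#'
#' The covariate model is
#' \deqn{CL = \theta_1 (CLCR/72)^{\theta_2} \quad (\mathrm{L/h}),}
#' replaced wholesale by `cl_crrt` or `cl_hd` for patients on continuous renal
#' replacement therapy or hemodialysis, and
#' \deqn{V_2 = \theta_3 (WT/60) \quad (\mathrm{L}),}
#' with fixed `v1` (central volume, L) and `q` (intercompartmental clearance,
#' L/h). BSV is log-normal on CL and V2: \eqn{P_i = P_{typ} e^{\eta_i}},
#' \eqn{\eta \sim N(0, \omega^2)}. The residual model is combined:
#' \eqn{Var = \sigma_{add}^2 + (\sigma_{prop} F)^2} for a model prediction
#' `F` (mg/L), with `sigma_add` and `sigma_prop` stored as standard
#' deviations.
#'
#' Between-subject variability is supplied on the CV% scale
#' (`omega_cl_cv`, `omega_v2_cv`) as conventionally reported, and converted
#' internally with [cv_to_omega2()].
#'
#' Defaults are the packaged estimates from a Korean TDM population (220
#' patients, 1020 observations); see [default_params()].
#'
#' @param theta1 Typical clearance (L/h) at the reference creatinine
#'   clearance of 72 mL/min.
#' @param theta2 Dimensionless power exponent on CLCR/72.
#' @param cl_crrt,cl_hd Fixed typical clearance (L/h) under CRRT / HD.
#' @param v1 Central volume (L).
#' @param q Intercompartmental clearance (L/h).
#' @param theta3 Typical peripheral volume (L) at the reference weight 60 kg.
#' @param omega_cl_cv,omega_v2_cv Between-subject variability of CL and V2,
#'   percent CV.
#' @param sigma_add Additive residual standard deviation (mg/L).
#' @param sigma_prop Proportional residual standard deviation
#'   (dimensionless).
#' @param ref_clcr,ref_wt Reference creatinine clearance (mL/min) and weight
#'   (kg) at which `theta1` and `theta3` are the typical values.
#'
#' @return An object of class `vanco_params`: a named list with the inputs
#'   plus the derived variances `omega2_cl` and `omega2_v2`.
#' @seealso [default_params()], [read_params()], [individual_params()]
#' @examples
#' p <- vanco_params()
#' p$theta1
#' omega2_to_cv(p$omega2_cl)
#' @export
vanco_params <- function(theta1 = 2.82, theta2 = 0.836,
                         cl_crrt = 0.716, cl_hd = 0.334,
                         v1 = 31.8, q = 11.7, theta3 = 75.4,
                         omega_cl_cv = 99.2, omega_v2_cv = 49.2,
                         sigma_add = 0, sigma_prop = 0.253,
                         ref_clcr = 72, ref_wt = 60) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      abort(paste0("`", nm, "` must be a single finite number"))
    as.numeric(x)
  }
  p <- list(
    theta1 = num1(theta1, "theta1"), theta2 = num1(theta2, "theta2"),
    cl_crrt = num1(cl_crrt, "cl_crrt"), cl_hd = num1(cl_hd, "cl_hd"),
    v1 = num1(v1, "v1"), q = num1(q, "q"), theta3 = num1(theta3, "theta3"),
    omega_cl_cv = num1(omega_cl_cv, "omega_cl_cv"),
    omega_v2_cv = num1(omega_v2_cv, "omega_v2_cv"),
    sigma_add = num1(sigma_add, "sigma_add"),
    sigma_prop = num1(sigma_prop, "sigma_prop"),
    ref_clcr = num1(ref_clcr, "ref_clcr"), ref_wt = num1(ref_wt, "ref_wt")
  )
  pos <- c("theta1", "cl_crrt", "cl_hd", "v1", "theta3", "ref_clcr", "ref_wt")
  for (nm in pos) if (p[[nm]] <= 0) abort(paste0("`", nm, "` must be > 0"))
  if (p$q < 0) abort("`q` must be >= 0")
  if (p$omega_cl_cv < 0 || p$omega_v2_cv < 0)
    abort("omega CV terms must be >= 0")
  if (p$sigma_add < 0 || p$sigma_prop < 0)
    abort("residual standard deviations must be >= 0")
  if (p$sigma_add == 0 && p$sigma_prop == 0)
    abort("degenerate residual model: sigma_add and sigma_prop are both 0")
  p$omega2_cl <- cv_to_omega2(p$omega_cl_cv)
  p$omega2_v2 <- cv_to_omega2(p$omega_v2_cv)
  structure(p, class = "vanco_params")
}

#' @export
print.vanco_params <- function(x, ...) {
  cat("<vanco_params> two-compartment vancomycin population model\n")
  cat(sprintf("  CL  = %.3g * (CLCR/%g)^%.3g L/h   (CRRT: %.3g, HD: %.3g)\n",
              x$theta1, x$ref_clcr, x$theta2, x$cl_crrt, x$cl_hd))
  cat(sprintf("  V1  = %.3g L, Q = %.3g L/h, V2 = %.3g * (WT/%g) L\n",
              x$v1, x$q, x$theta3, x$ref_wt))
  cat(sprintf("  BSV: omega_CL %.3g%% CV, omega_V2 %.3g%% CV\n",
              x$omega_cl_cv, x$omega_v2_cv))
  cat(sprintf("  Residual: sd_add %.3g mg/L, sd_prop %.3g\n",
              x$sigma_add, x$sigma_prop))
  invisible(x)
}

#' Packaged default population model
#'
#' Loads the parameter file shipped with the package
#' (`inst/extdata/vanco-params.yaml`), the final population estimates from a
#' Korean vancomycin TDM population.
#'
#' @return A [vanco_params()] object.
#' @examples
#' default_params()
#' @export
default_params <- function() {
  read_params(system.file("extdata", "vanco-params.yaml",
                          package = "vancotdm", mustWork = TRUE))
}

#' Read population parameters from a YAML or JSON file
#'
#' The file is a flat key-value mapping with keys `theta1`, `theta2`,
#' `cl_crrt`, `cl_hd`, `v1`, `q`, `theta3`, `omega_cl_cv`, `omega_v2_cv`,
#' `sigma_add`, `sigma_prop` (and optionally `ref_clcr`, `ref_wt`).
#' Omega entries are CV percentages and are converted to variances on load.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [vanco_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(vanco_params))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warn(paste0("ignoring unknown parameter keys: ",
                paste(extra, collapse = ", ")))
  do.call(vanco_params, raw[intersect(names(raw), known)])
}

#' Write population parameters to a YAML file
#'
#' @param params A [vanco_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "vanco_params"))
  keep <- c("theta1", "theta2", "cl_crrt", "cl_hd", "v1", "q", "theta3",
            "omega_cl_cv", "omega_v2_cv", "sigma_add", "sigma_prop",
            "ref_clcr", "ref_wt")
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}

#' Convert between percent CV and log-normal variance
#'
#' For a log-normally distributed parameter \eqn{P = P_{typ} e^{\eta}},
#' \eqn{\eta \sim N(0, \omega^2)}, the coefficient of variation of `P` is
#' \eqn{CV = \sqrt{e^{\omega^2} - 1}}. `cv_to_omega2()` inverts this:
#' \eqn{\omega^2 = \ln(1 + (CV/100)^2)}. The two functions are exact
#' inverses.
#'
#' @param cv_percent Coefficient of variation, percent (>= 0).
#' @param omega2 Log-scale variance (>= 0).
#' @return `cv_to_omega2()`: the variance; `omega2_to_cv()`: the percent CV.
#' @examples
#' cv_to_omega2(99.2)
#' omega2_to_cv(cv_to_omega2(49.2))
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0))
    abort("`cv_percent` must be finite and >= 0")
  log1p((cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0))
    abort("`omega2` must be finite and >= 0")
  100 * sqrt(expm1(omega2))
}
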