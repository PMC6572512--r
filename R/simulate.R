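#' Draw between-subject random effects
#'
#' Independent draws `eta_cl ~ N(0, omega2_cl)`, `eta_v2 ~ N(0, omega2_v2)`.
#' Reproducible for a given `seed`; with a zero omega the corresponding
#' column is exactly 0.
#'
#' @param params A [vanco_params()] object.
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed (local to this call).
#' @return A tibble with columns `eta_cl`, `eta_v2`.
#' @export
draw_etas <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "vanco_params"), n >= 1)
  draw <- function() tibble::tibble(
    eta_cl = rnorm(n, 0, sqrt(params$omega2_cl)),
    eta_v2 = rnorm(n, 0, sqrt(params$omega2_v2)))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The four renal-function scenario groups
#'
#' Virtual-patient templates for the standard simulation experiment: all
#' weigh 60 kg and receive 1 g vancomycin daily for 7 days as 1-h infusions.
#' Group 1: CLCR 100 mL/min (normal renal function); Group 2: CLCR 40 mL/min
#' (moderate impairment); Group 3: CRRT; Group 4: HD.
#'
#' @return A patient table with a `label` column, one row per group.
#' @examples
#' scenario_groups()
#' @export
scenario_groups <- function() {
  dplyr::bind_cols(
    tibble::tibble(label = c("Group 1 (CLCR 100)", "Group 2 (CLCR 40)",
                             "Group 3 (CRRT)", "Group 4 (HD)")),
    patients(age = 60, sex = "male", weight = 60,
             clcr = c(100, 40, NA, NA),
             hd = c(FALSE, FALSE, FALSE, TRUE),
             crrt = c(FALSE, FALSE, TRUE, FALSE))
  )
}

#' Monte-Carlo population simulation of a dosing scenario
#'
#' Simulates `n_subjects` virtual patients sharing the covariates of
#' `patient`: each draws `(eta_cl, eta_v2)` from the BSV distribution, gets
#' individual parameters, and has its concentration curve evaluated on a
#' regular grid. The pointwise median and 90% prediction interval
#' (5th/95th percentiles) summarize the population; per-subject
#' steady-state metrics (`cpeak`, `ctrough`, `auc24`) are retained.
#'
#' By default curves are error-free true-concentration profiles (population
#' variability only); set `include_residual_error = TRUE` to add combined
#' residual noise to the gridded concentrations, as when emulating observed
#' TDM samples.
#'
#' @param patient Single-row patient table (a `label` column is carried
#'   through if present).
#' @param reg A [regimen()].
#' @param params A [vanco_params()] object.
#' @param n_subjects Number of virtual subjects.
#' @param seed Optional integer seed.
#' @param include_residual_error Add residual measurement noise to the grid?
#' @param dt Grid spacing, h.
#' @param t_end Grid end, h; default the end of the last dosing interval.
#' @return An object of class `vanco_sim`: list with `profiles` (tibble
#'   `time`, `median`, `p5`, `p95`), `metrics` (per-subject `eta_cl`,
#'   `eta_v2`, `cl`, `v2`, `cpeak`, `ctrough`, `auc24`) and the call
#'   settings. Supports [autoplot()] and [glance()].
#' @examples
#' g1 <- scenario_groups()[1, ]
#' sim <- simulate_population(g1, regimen(1000, 24, 7, 1), vanco_params(),
#'                            n_subjects = 100, seed = 1)
#' glance(sim)
#' @export
simulate_population <- function(patient, reg, params, n_subjects = 1000,
                                seed = NULL, include_residual_error = FALSE,
                                dt = 0.25, t_end = NULL) {
  stopifnot(inherits(params, "vanco_params"), n_subjects >= 1)
  if (nrow(patient) != 1L) abort("`patient` must be a single template row")
  reg <- as_regimen(reg)
  run <- function() {
    eta <- draw_etas(params, n_subjects)
    ip <- individual_params(patient[, setdiff(names(patient), "label")],
                            params, eta = eta)
    t_last <- reg$start_time[nrow(reg)]
    t_stop <- t_end %||%
      (t_last + if (nrow(reg) >= 2L) last_interval(reg) else 24)
    grid <- seq(0, t_stop, by = dt)
    if (tail(grid, 1L) < t_stop) grid <- c(grid, t_stop)
    cm <- .conc_matrix(ip$cl, ip$v1, ip$q, ip$v2, reg, grid)
    if (include_residual_error) {
      sdm <- sqrt(params$sigma_add^2 + (params$sigma_prop * cm)^2)
      cm <- pmax(cm + sdm * rnorm(length(cm)), 0)
    }
    qs <- apply(cm, 2L, quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
    profiles <- tibble::tibble(time = grid, median = qs[2L, ],
                               p5 = qs[1L, ], p95 = qs[3L, ])
    metrics <- dplyr::bind_cols(
      ip[, c("eta_cl", "eta_v2", "cl", "v2")],
      steady_state_metrics(ip, reg))
    list(profiles = profiles, metrics = metrics)
  }
  res <- if (is.null(seed)) run() else with_local_seed(seed, run())
  structure(c(res, list(
    label = if ("label" %in% names(patient)) patient$label else NA_character_,
    n_subjects = n_subjects, seed = seed, regimen = reg,
    include_residual_error = include_residual_error
  )), class = "vanco_sim")
}

#' @export
print.vanco_sim <- function(x, ...) {
  cat("<vanco_sim>", if (!is.na(x$label)) x$label else "", "\n")
  cat(sprintf("  %d virtual subjects, %d doses, grid of %d times\n",
              x$n_subjects, nrow(x$regimen), nrow(x$profiles)))
  print(glance(x))
  invisible(x)
}

#' @rdname simulate_population
#' @param x A `vanco_sim` object.
#' @param ... Unused.
#' @export
glance.vanco_sim <- function(x, ...) {
  tibble::tibble(
    median_cpeak = median(x$metrics$cpeak),
    median_ctrough = median(x$metrics$ctrough),
    median_auc24 = median(x$metrics$auc24),
    n_subjects = x$n_subjects
  )
}

#' @rdname simulate_population
#' @param object A `vanco_sim` object.
#' @export
autoplot.vanco_sim <- function(object, ...) {
  ggplot2::ggplot(object$profiles, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(
      x = "Time (h)", y = "Vancomycin concentration (mg/L)",
      title = if (!is.na(object$label)) object$label else "Population simulation",
      subtitle = sprintf("median and 90%% prediction interval, n = %d",
                         object$n_subjects)) +
    ggplot2::theme_minimal()
}
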