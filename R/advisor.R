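#' Therapeutic target specification
#'
#' Vancomycin exposure targets for regimen evaluation. Defaults are the
#' general adult targets: steady-state trough 10-20 mg/L and AUC over the
#' final 24 h of at least 400 mg·h/L; an optional peak ceiling can be set.
#' All ranges are user-adjustable per indication.
#'
#' @param trough_low,trough_high Trough window bounds, mg/L
#'   (`trough_low < trough_high`).
#' @param auc24_min Minimum AUC24, mg·h/L; `NA` disables the AUC criterion.
#' @param peak_max Maximum peak, mg/L; `Inf` disables the ceiling.
#' @return A list of class `vanco_target`.
#' @examples
#' vanco_target()
#' vanco_target(trough_low = 15, trough_high = 20)
#' @export
vanco_target <- function(trough_low = 10, trough_high = 20,
                         auc24_min = 400, peak_max = Inf) {
  if (trough_low < 0 || trough_high <= trough_low)
    abort("need 0 <= trough_low < trough_high")
  if (!is.na(auc24_min) && auc24_min <= 0) abort("`auc24_min` must be > 0")
  if (peak_max <= 0) abort("`peak_max` must be > 0")
  structure(list(trough_low = trough_low, trough_high = trough_high,
                 auc24_min = auc24_min, peak_max = peak_max),
            class = "vanco_target")
}

#' Evaluate a regimen against therapeutic targets
#'
#' Computes the steady-state exposure metrics of [steady_state_metrics()]
#' for one individual under one regimen and flags target attainment.
#'
#' @param ip Single-row individual parameter table (`cl`, `v1`, `q`, `v2`).
#' @param reg A [regimen()].
#' @param target A [vanco_target()].
#' @return One-row tibble: `cpeak`, `ctrough`, `auc24`, `meets_trough`,
#'   `meets_auc`, `meets_peak`, `meets_all`.
#' @examples
#' ip <- individual_params(patients(age = 60, sex = "male", weight = 60,
#'                                  clcr = 100), vanco_params())
#' evaluate_regimen(ip, regimen(1000, 24, 7, 1), vanco_target())
#' @export
evaluate_regimen <- function(ip, reg, target = vanco_target()) {
  stopifnot(inherits(target, "vanco_target"))
  m <- steady_state_metrics(ip, reg)
  dplyr::mutate(
    m,
    meets_trough = .data$ctrough >= target$trough_low &
      .data$ctrough <= target$trough_high,
    meets_auc = if (is.na(target$auc24_min)) TRUE
                else .data$auc24 >= target$auc24_min,
    meets_peak = .data$cpeak <= target$peak_max,
    meets_all = .data$meets_trough & .data$meets_auc & .data$meets_peak
  )
}

#' Grid search for regimens attaining the targets
#'
#' Exhaustively evaluates every combination of candidate dose, dosing
#' interval and infusion duration for one individual over a fixed treatment
#' horizon, and returns the combinations meeting all targets, ranked by
#' closeness of the trough to the middle of the trough window. Ties break
#' deterministically toward the lower dose, then the longer interval, so the
#' ranking does not depend on grid enumeration order.
#'
#' @inheritParams evaluate_regimen
#' @param doses Candidate doses, mg.
#' @param intervals Candidate dosing intervals, h.
#' @param durations Candidate infusion durations, h.
#' @param horizon Treatment horizon over which steady state is approached, h
#'   (default 168 = 7 days); the last full interval inside the horizon is
#'   evaluated.
#' @return A tibble of passing candidates (`dose`, `interval`, `duration`,
#'   `cpeak`, `ctrough`, `auc24`, attainment flags), best first. When no
#'   candidate passes, a zero-row tibble with
#'   `attr(., "note") = "no regimen meets targets"`; the full evaluated grid
#'   is always available as `attr(., "evaluated")`.
#' @examples
#' ip <- individual_params(patients(age = 60, sex = "male", weight = 60,
#'                                  clcr = 100), vanco_params())
#' search_regimens(ip, doses = c(1000, 1500), intervals = c(12, 24),
#'                 durations = 1)
#' @export
search_regimens <- function(ip, doses = c(500, 750, 1000, 1250, 1500),
                            intervals = c(8, 12, 24), durations = c(1, 2),
                            target = vanco_target(), horizon = 168) {
  if (!length(doses) || !length(intervals) || !length(durations))
    abort("candidate grids must be non-empty")
  if (any(durations > min(intervals)))
    abort("infusion durations must not exceed the shortest candidate interval")
  grid <- tidyr::expand_grid(dose = sort(unique(doses)),
                             interval = sort(unique(intervals)),
                             duration = sort(unique(durations)))
  evaluated <- purrr::pmap_dfr(grid, function(dose, interval, duration) {
    n_doses <- max(floor(horizon / interval), 2L)
    reg <- regimen(dose, interval, n_doses, duration)
    dplyr::bind_cols(tibble::tibble(dose = dose, interval = interval,
                                    duration = duration),
                     evaluate_regimen(ip, reg, target))
  })
  mid <- (target$trough_low + target$trough_high) / 2
  passing <- evaluated |>
    dplyr::filter(.data$meets_all) |>
    dplyr::arrange(abs(.data$ctrough - mid), .data$dose,
                   dplyr::desc(.data$interval), .data$duration)
  if (nrow(passing) == 0L) {
    message("no regimen in the candidate grid meets all targets")
    attr(passing, "note") <- "no regimen meets targets"
  }
  attr(passing, "evaluated") <- evaluated
  passing
}
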