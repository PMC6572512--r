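#' Intravenous infusion dosing histories
#'
#' A regimen is a tibble of timed zero-order IV infusions with columns
#' `start_time` (h since first dose), `amount` (mg) and `duration` (h).
#' `regimen()` builds a repeating schedule; `dose_events()` builds an
#' arbitrary history.
#'
#' @param amount Dose per administration, mg (> 0).
#' @param interval Dosing interval, h (> 0).
#' @param n_doses Number of doses.
#' @param duration Infusion duration, h (> 0).
#' @param start First-dose time, h.
#' @return A tibble of class `vanco_regimen`, sorted by `start_time`.
#' @examples
#' regimen(1000, interval = 24, n_doses = 7, duration = 1)
#' @export
regimen <- function(amount = 1000, interval = 24, n_doses = 7,
                    duration = 1, start = 0) {
  stopifnot(interval > 0, n_doses >= 1)
  dose_events(start_time = start + interval * (seq_len(n_doses) - 1),
              amount = amount, duration = duration)
}

#' @rdname regimen
#' @param start_time Vector of infusion start times, h (>= 0).
#' @export
dose_events <- function(start_time, amount, duration) {
  out <- tibble::tibble(start_time = as.numeric(start_time),
                        amount = as.numeric(amount),
                        duration = as.numeric(duration))
  if (nrow(out) == 0L) abort("a regimen must contain at least one dose")
  if (any(out$amount <= 0)) abort("dose `amount` must be > 0")
  if (any(out$duration <= 0)) abort("infusion `duration` must be > 0")
  if (any(out$start_time < 0)) abort("`start_time` must be >= 0")
  out <- dplyr::arrange(out, .data$start_time)
  class(out) <- c("vanco_regimen", class(out))
  out
}

as_regimen <- function(x) {
  if (inherits(x, "vanco_regimen")) return(x)
  dose_events(x$start_time, x$amount, x$duration)
}

# Dosing interval implied by the tail of the schedule (h).
last_interval <- function(reg) {
  if (nrow(reg) < 2L)
    abort("regimen has a single dose: no dosing interval is defined")
  diff(tail(reg$start_time, 2L))
}
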