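#' Simulate a synthetic TDM dataset with known individual truth
#'
#' Generates a NONMEM-style dataset of virtual patients for testing and
#' demonstration, together with the subject-level truth (the etas and
#' individual parameters that produced it) for parameter-recovery studies.
#' Covariates are drawn uniformly from ranges spanning a routine hospital
#' TDM population (age 21-98 y, weight 30-126.7 kg, CLCR 4.57-279 mL/min by
#' default), etas from the model's BSV distribution, and observations from
#' the combined residual-error model at typical TDM sampling times (a peak
#' about 1 h after the end of an infusion and/or a pre-dose trough on
#' randomly chosen treatment days).
#'
#' @param params A [vanco_params()] object.
#' @param n_subjects Number of virtual subjects.
#' @param seed Optional integer seed; a fixed seed gives identical output.
#' @param obs_per_subject Range (length-2 integer) of observations sampled
#'   per subject.
#' @param age_range,wt_range,clcr_range Covariate ranges.
#' @param hd_fraction,crrt_fraction Fractions of subjects on HD / CRRT
#'   (mutually exclusive assignments).
#' @param amount,interval,n_doses,duration Regimen shared by all subjects
#'   (mg, h, count, h).
#' @return A list with `data` (a `tdm_dataset`) and `truth` (tibble `ID`,
#'   `eta_cl`, `eta_v2`, `cl`, `v1`, `q`, `v2`).
#' @seealso [generate_fixtures()] to write both to disk.
#' @export
simulate_tdm_dataset <- function(params, n_subjects = 20, seed = NULL,
                                 obs_per_subject = c(3, 6),
                                 age_range = c(21, 98),
                                 wt_range = c(30, 126.7),
                                 clcr_range = c(4.57, 279),
                                 hd_fraction = 0, crrt_fraction = 0,
                                 amount = 1000, interval = 24, n_doses = 7,
                                 duration = 1) {
  stopifnot(inherits(params, "vanco_params"), n_subjects >= 1)
  if (hd_fraction + crrt_fraction > 1)
    abort("hd_fraction + crrt_fraction must be <= 1")
  run <- function() {
    regime <- sample(c("hd", "crrt", "none"), n_subjects, replace = TRUE,
                     prob = c(hd_fraction, crrt_fraction,
                              1 - hd_fraction - crrt_fraction))
    pats <- patients(
      age = runif(n_subjects, age_range[1L], age_range[2L]),
      sex = sample(c("male", "female"), n_subjects, replace = TRUE),
      weight = runif(n_subjects, wt_range[1L], wt_range[2L]),
      clcr = ifelse(regime == "none",
                    runif(n_subjects, clcr_range[1L], clcr_range[2L]),
                    NA_real_),
      hd = regime == "hd", crrt = regime == "crrt"
    )
    eta <- draw_etas(params, n_subjects)
    ip <- individual_params(pats, params, eta = eta)
    reg <- regimen(amount, interval, n_doses, duration)

    # candidate TDM sampling times: post-infusion peak and pre-dose trough
    peak_t <- reg$start_time + reg$duration + 1
    trough_t <- reg$start_time[-1L] - 0.1
    cand <- sort(c(peak_t, trough_t))

    rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      n_obs <- sample(seq(obs_per_subject[1L], obs_per_subject[2L]), 1L)
      t_obs <- sort(sample(cand, min(n_obs, length(cand))))
      f <- predict_conc(ip[i, ], reg, t_obs)$conc
      sdm <- sqrt(residual_variance(params, f))
      dv <- f + sdm * rnorm(length(f))
      while (any(dv <= 0)) {  # resample nonphysical negatives (rare)
        bad <- dv <= 0
        dv[bad] <- f[bad] + sdm[bad] * rnorm(sum(bad))
      }
      dplyr::bind_rows(
        tibble::tibble(ID = i, TIME = reg$start_time, EVID = 1,
                       AMT = reg$amount, DUR = reg$duration,
                       DV = NA_real_, MDV = 1),
        tibble::tibble(ID = i, TIME = t_obs, EVID = 0, AMT = NA_real_,
                       DUR = NA_real_, DV = dv, MDV = 0)
      ) |>
        dplyr::arrange(.data$TIME, dplyr::desc(.data$EVID)) |>
        dplyr::mutate(
          AGE = pats$age[i], SEX = as.integer(pats$sex[i] == "female"),
          WT = pats$weight[i], SCR = pats$scr[i], CLCR = pats$clcr[i],
          HD = as.integer(pats$hd[i]), CRRT = as.integer(pats$crrt[i]))
    })
    list(
      data = as_tdm(rows),
      truth = dplyr::bind_cols(tibble::tibble(ID = seq_len(n_subjects)),
                               ip[, c("eta_cl", "eta_v2", "cl", "v1", "q", "v2")])
    )
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Write a synthetic TDM fixture to disk
#'
#' Runs [simulate_tdm_dataset()] and writes `dataset.csv` plus a
#' `truth.csv` of per-subject etas and parameters into `dir`. Output is
#' byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param ... Passed to [simulate_tdm_dataset()].
#' @param seed Integer seed (required, for reproducibility).
#' @param params A [vanco_params()] object.
#' @return Named character vector of the two file paths, invisibly.
#' @export
generate_fixtures <- function(dir, params = default_params(), seed, ...) {
  if (missing(seed)) abort("`seed` is required for reproducible fixtures")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- simulate_tdm_dataset(params, seed = seed, ...)
  paths <- c(dataset = file.path(dir, "dataset.csv"),
             truth = file.path(dir, "truth.csv"))
  write_tdm(fx$data, paths[["dataset"]])
  readr::write_csv(fx$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
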