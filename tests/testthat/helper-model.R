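# Shared fixtures: built in code, no files.

pop <- vanco_params()  # packaged defaults (Table-of-estimates values)

pat_g1 <- patients(age = 60, sex = "male", weight = 60, clcr = 100)
pat_ref <- patients(age = 60, sex = "male", weight = 60, clcr = 72)

reg_std <- regimen(1000, interval = 24, n_doses = 7, duration = 1)

ip_g1 <- individual_params(pat_g1, pop)[, c("cl", "v1", "q", "v2")]

# Independent brute-force evaluation of the MAP objective: a deliberately
# plain re-implementation (scalar loops, no shared helpers beyond the
# concentration prediction input F computed by the oracle ODE path).
brute_force_objective <- function(eta, obs, patient, reg, params) {
  ecl <- eta[1]; ev2 <- eta[2]
  p1 <- if (!patient$hd && !patient$crrt && is.na(patient$clcr))
    compute_clcr(patient) else patient
  cl_typ <- if (p1$crrt) params$cl_crrt else if (p1$hd) params$cl_hd else
    params$theta1 * (p1$clcr / params$ref_clcr)^params$theta2
  ip <- tibble::tibble(cl = cl_typ * exp(ecl), v1 = params$v1, q = params$q,
                       v2 = params$theta3 * (p1$weight / params$ref_wt) * exp(ev2))
  total <- 0
  for (j in seq_len(nrow(obs))) {
    fj <- ode_conc(ip, reg, obs$time[j])$conc
    s2 <- params$sigma_add^2 + (params$sigma_prop * fj)^2
    total <- total + log(s2) + (obs$conc[j] - fj)^2 / s2
  }
  total + ecl^2 / params$omega2_cl + ev2^2 / params$omega2_v2
}

# Model-simulated TDM dataset with one observation per default VPC bin for
# every subject, so all 14 bins are populated (long course: 38 daily doses).
make_vpc_dataset <- function(n_subjects = 24, seed = 7, params = pop) {
  reg <- regimen(1000, 24, 38, 1)
  t_obs <- c(4, 10, 20, 36, 60, 88, 150, 250, 350, 450, 550, 650, 750, 850)
  withr::with_seed(seed, {
    eta <- draw_etas(params, n_subjects)
    rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
      pat <- patients(age = 50 + i, sex = "male", weight = 55 + i, clcr = 60 + 2 * i)
      ip <- individual_params(pat, params, eta[i, ])
      f <- predict_conc(ip[, c("cl", "v1", "q", "v2")], reg, t_obs)$conc
      dv <- f + sqrt(residual_variance(params, f)) * rnorm(length(f))
      dv <- pmax(dv, 0.05)
      dplyr::bind_rows(
        tibble::tibble(ID = i, TIME = reg$start_time, EVID = 1,
                       AMT = 1000, DUR = 1, DV = NA_real_, MDV = 1),
        tibble::tibble(ID = i, TIME = t_obs, EVID = 0, AMT = NA_real_,
                       DUR = NA_real_, DV = dv, MDV = 0)
      ) |>
        dplyr::arrange(TIME, dplyr::desc(EVID)) |>
        dplyr::mutate(AGE = pat$age, SEX = 0, WT = pat$weight,
                      SCR = NA_real_, CLCR = pat$clcr, HD = 0, CRRT = 0)
    })
    as_tdm(rows)
  })
}
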