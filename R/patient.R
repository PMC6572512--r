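#' Build a patient covariate table
#'
#' One row per patient. Serum creatinine may be omitted when `clcr` is given
#' directly, and neither is needed for patients on hemodialysis or CRRT
#' (whose clearance is regime-determined).
#'
#' @param age Age, years (> 0).
#' @param sex `"male"` or `"female"` (used only by Cockcroft-Gault).
#' @param weight Body weight, kg (> 0).
#' @param scr Serum creatinine, mg/dL (optional).
#' @param clcr Creatinine clearance, mL/min (optional; overrides the
#'   Cockcroft-Gault value when supplied).
#' @param hd,crrt Logical renal-replacement flags; mutually exclusive.
#' @return A tibble with columns `age`, `sex`, `weight`, `scr`, `clcr`,
#'   `hd`, `crrt`.
#' @examples
#' patients(age = 63, sex = "male", weight = 60, clcr = 100)
#' @export
patients <- function(age, sex, weight, scr = NA_real_, clcr = NA_real_,
                     hd = FALSE, crrt = FALSE) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    abort('`sex` must be "male" or "female"')
  out <- tibble::tibble(
    age = as.numeric(age), sex = sex, weight = as.numeric(weight),
    scr = as.numeric(scr), clcr = as.numeric(clcr),
    hd = as.logical(hd), crrt = as.logical(crrt)
  )
  validate_patients(out)
  out
}

validate_patients <- function(p) {
  req <- c("age", "sex", "weight", "scr", "clcr", "hd", "crrt")
  miss <- setdiff(req, names(p))
  if (length(miss))
    abort(paste0("patient table is missing columns: ",
                 paste(miss, collapse = ", ")))
  if (any(p$hd & p$crrt))
    abort("`hd` and `crrt` are mutually exclusive: a single clearance regime applies")
  bad <- !is.na(p$weight) & p$weight <= 0
  if (any(bad) || any(is.na(p$weight))) abort("`weight` must be present and > 0")
  if (any(is.na(p$age)) || any(p$age <= 0)) abort("`age` must be present and > 0")
  if (any(!is.na(p$scr) & p$scr <= 0)) abort("`scr` must be > 0 when present")
  if (any(!is.na(p$clcr) & p$clcr <= 0)) abort("`clcr` must be > 0 when present")
  need_renal <- !p$hd & !p$crrt
  if (any(need_renal & is.na(p$scr) & is.na(p$clcr)))
    abort(paste0("insufficient covariates: patients without HD/CRRT need ",
                 "`scr` or `clcr`"))
  invisible(p)
}

#' Cockcroft-Gault creatinine clearance
#'
#' Fills the `clcr` column of a patient table using the Cockcroft-Gault
#' equation,
#' \deqn{CLCR = \frac{(140 - age)\, WT}{72\, S_{cr}} \times (0.85\
#' \mathrm{if\ female})\quad \mathrm{mL/min},}
#' with age in years, weight in kg and serum creatinine in mg/dL. Rows that
#' already carry an explicit `clcr` are returned unchanged; the equation is
#' never silently defaulted when covariates are missing.
#'
#' @param p A patient table as from [patients()].
#' @return `p` with `clcr` filled for every row.
#' @examples
#' compute_clcr(patients(age = 40, sex = "male", weight = 72, scr = 1))$clcr
#' @export
compute_clcr <- function(p) {
  validate_patients(p)
  need <- is.na(p$clcr)
  if (any(need & (is.na(p$scr) | is.na(p$age) | is.na(p$weight))))
    abort("insufficient covariates for Cockcroft-Gault: need age, weight, sex, scr")
  cg <- (140 - p$age) * p$weight / (72 * p$scr)
  cg <- ifelse(p$sex == "female", 0.85 * cg, cg)
  dplyr::mutate(p, clcr = ifelse(need, cg, .data$clcr))
}
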