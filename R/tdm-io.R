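#' Read a NONMEM-style TDM dataset
#'
#' Reads the rectangular CSV layout standard in pharmacometrics: one row per
#' dosing or observation event. Mandatory columns: `ID`, `TIME` (h since
#' first dose, per subject), `EVID` (0 = observation, 1 = dose), `AMT` (mg,
#' dose rows), one of `DUR` (h) or `RATE` (mg/h, converted to `DUR =
#' AMT/RATE`), `DV` (mg/L, observation rows), `AGE` (years), `SEX` (0 =
#' male, 1 = female), `WT` (kg), and one of `SCR` (mg/dL) or `CLCR`
#' (mL/min). Optional: `MDV` (1 = missing DV), `HD`, `CRRT` (0/1 regime
#' flags). Unknown columns are preserved but ignored.
#'
#' Validation is strict: rows violating the invariants are reported with
#' their row numbers, and `HD = 1` with `CRRT = 1` on the same subject is a
#' hard error.
#'
#' @param path CSV file path.
#' @return A validated tibble of class `tdm_dataset`.
#' @seealso [write_tdm()], [tdm_subjects()], [apply_outlier_filter()]
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) abort(paste0("dataset not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_tdm(df)
}

#' @rdname read_tdm
#' @param df A data frame in the layout above (e.g. assembled in code).
#' @export
as_tdm <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("ID", "TIME", "EVID", "AMT", "DV", "AGE", "SEX", "WT")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("dataset is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  if (!("DUR" %in% names(df)) && !("RATE" %in% names(df)))
    abort("dataset is missing mandatory column(s): DUR or RATE")
  if (!("SCR" %in% names(df)) && !("CLCR" %in% names(df)))
    abort("dataset is missing mandatory column(s): SCR or CLCR")
  if (!("MDV" %in% names(df))) df$MDV <- 0
  if (!("HD" %in% names(df))) df$HD <- 0
  if (!("CRRT" %in% names(df))) df$CRRT <- 0
  if (!("SCR" %in% names(df))) df$SCR <- NA_real_
  if (!("CLCR" %in% names(df))) df$CLCR <- NA_real_
  df$MDV[is.na(df$MDV)] <- 0
  if (!("DUR" %in% names(df))) df$DUR <- NA_real_
  if ("RATE" %in% names(df)) {
    use <- df$EVID == 1 & is.na(df$DUR) & !is.na(df$RATE)
    df$DUR[use] <- df$AMT[use] / df$RATE[use]
  }

  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      abort(paste0("invalid dataset: ", what, " at row(s) ",
                   paste(head(idx, 10L), collapse = ", ")))
  }
  bad_rows(!(df$EVID %in% c(0, 1)), "EVID must be 0 or 1")
  bad_rows(is.na(df$TIME) | df$TIME < 0, "TIME must be >= 0")
  bad_rows(df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0),
           "dose rows need AMT > 0")
  bad_rows(df$EVID == 1 & (is.na(df$DUR) | df$DUR <= 0),
           "dose rows need DUR > 0 (or RATE)")
  bad_rows(df$EVID == 0 & df$MDV != 1 & (is.na(df$DV) | df$DV <= 0),
           "observation rows need DV > 0 unless MDV = 1")
  backstep <- stats::ave(df$TIME, df$ID,
                         FUN = function(t) c(0, as.numeric(diff(t) < 0)))
  bad_rows(backstep == 1, "TIME must be nondecreasing within ID")
  per_id <- dplyr::summarise(dplyr::group_by(df, .data$ID),
                             has_dose = any(.data$EVID == 1),
                             hd = any(.data$HD == 1),
                             crrt = any(.data$CRRT == 1))
  if (any(!per_id$has_dose))
    abort(paste0("invalid dataset: no dose row for ID(s) ",
                 paste(per_id$ID[!per_id$has_dose], collapse = ", ")))
  if (any(per_id$hd & per_id$crrt))
    abort(paste0("invalid dataset: HD and CRRT both set for ID(s) ",
                 paste(per_id$ID[per_id$hd & per_id$crrt], collapse = ", ")))
  class(df) <- unique(c("tdm_dataset", class(df)))
  df
}

#' Write a TDM dataset to CSV
#'
#' @param dataset A `tdm_dataset` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tdm <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset), path, progress = FALSE)
  invisible(path)
}

#' Exclude outlier concentrations
#'
#' Drops observation rows whose `DV` strictly exceeds `ceiling` (default
#' 100 mg/L, the assay outlier ceiling of the source population analysis).
#' Dose rows are never touched. The number of excluded rows is attached as
#' attribute `n_excluded`.
#'
#' @param dataset A `tdm_dataset`.
#' @param ceiling Concentration ceiling, mg/L (> 0).
#' @return The filtered dataset, with `attr(., "n_excluded")`.
#' @examples
#' \dontrun{
#' filtered <- apply_outlier_filter(ds, ceiling = 100)
#' attr(filtered, "n_excluded")
#' }
#' @export
apply_outlier_filter <- function(dataset, ceiling = 100) {
  if (ceiling <= 0) abort("`ceiling` must be > 0")
  drop <- dataset$EVID == 0 & dataset$MDV != 1 &
    !is.na(dataset$DV) & dataset$DV > ceiling
  out <- dataset[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Split a TDM dataset into per-subject model inputs
#'
#' Nests the rectangular dataset into one row per subject with list-columns
#' holding the pieces the estimation and simulation functions consume: a
#' single-row [patients()] table (covariates from the subject's first row),
#' a [regimen()] of the subject's dose rows, and an observation tibble
#' (`time`, `conc`) of non-missing DV rows.
#'
#' @param dataset A `tdm_dataset`.
#' @return A tibble with columns `id`, `patient`, `regimen`, `obs`.
#' @export
tdm_subjects <- function(dataset) {
  dataset |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$ID) |>
    dplyr::group_map(function(g, key) {
      pat <- patients(
        age = g$AGE[1L],
        sex = ifelse(g$SEX[1L] == 1, "female", "male"),
        weight = g$WT[1L],
        scr = g$SCR[1L],
        clcr = g$CLCR[1L],
        hd = g$HD[1L] == 1,
        crrt = g$CRRT[1L] == 1
      )
      dose <- g[g$EVID == 1, ]
      ob <- g[g$EVID == 0 & g$MDV != 1 & !is.na(g$DV), ]
      tibble::tibble(
        id = key$ID,
        patient = list(pat),
        regimen = list(dose_events(dose$TIME, dose$AMT, dose$DUR)),
        obs = list(tibble::tibble(time = ob$TIME, conc = ob$DV))
      )
    }) |>
    dplyr::bind_rows()
}
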