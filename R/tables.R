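#' Paths to the bundled cohort tables
#'
#' The package ships the published per-patient tables of a 12-patient
#' apical-lung SBRT cohort (6 free-breathing, 6 breath-hold), which drive
#' the cohort-level operations:
#'
#' * `motion_table.csv` — per-patient motion SDs (cm) on the simulation
#'   cine and the mean/min/max over the treatment fractions, per axis,
#'   with the gating technique used.
#' * `patient_table.csv` — free-breathing patients' CC motion SD next to
#'   lung volume, GTV volume, their ratio (x 1e-4) and the peak-to-peak
#'   hepatic dome excursion.
#' * `dvh_table.csv` — per-patient DVH-index differences between plans
#'   with the 3 mm and 5 mm GTV-to-PTV margins (narrow minus standard).
#'
#' @param file file name, or `NULL` to list the available files.
#' @return a file path (or a character vector of file names).
#' @export
cinegate_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "cinegate")))
  path <- system.file("extdata", file, package = "cinegate")
  if (path == "")
    stopf("no bundled file '%s'", file, class = "cinegate_io_error")
  path
}

#' Read a per-patient motion summary table
#'
#' @param path CSV with columns `patient`, `gating`, then
#'   `sim`/`mean`/`min`/`max` SDs (cm) for the AP and CC axes. Defaults to
#'   the bundled cohort.
#' @return a data frame.
#' @export
read_motion_table <- function(path = cinegate_example("motion_table.csv")) {
  tbl <- utils::read.csv(path)
  need <- c("patient", "gating", "sim_ap", "mean_ap", "min_ap", "max_ap",
            "sim_cc", "mean_cc", "min_cc", "max_cc")
  if (!all(need %in% names(tbl)))
    stopf("motion table needs columns %s", paste(need, collapse = ", "),
          class = "cinegate_format_error")
  tbl
}

#' @describeIn read_motion_table Convert the table rows into
#'   `patient_motion_summary` objects (per-fraction detail is not part of
#'   the table, so `per_fraction` is `NULL`).
#' @param tbl a motion table data frame.
#' @export
patient_summaries <- function(tbl = read_motion_table()) {
  lapply(seq_len(nrow(tbl)), function(i)
    patient_motion_summary(
      patient_id = tbl$patient[i],
      sim = c(ap = tbl$sim_ap[i], cc = tbl$sim_cc[i]),
      mean = c(ap = tbl$mean_ap[i], cc = tbl$mean_cc[i]),
      min = c(ap = tbl$min_ap[i], cc = tbl$min_cc[i]),
      max = c(ap = tbl$max_ap[i], cc = tbl$max_cc[i]),
      gating = tbl$gating[i]))
}

#' Read the anatomical-surrogate table
#'
#' @param path CSV with columns `patient`, `gtv_motion_cc`, `v_lung_cc`,
#'   `v_gtv_cc`, `ratio_gtv_lung_1e4`, `hepatic_dome_motion_cm`. Defaults
#'   to the bundled free-breathing cohort.
#' @return a data frame.
#' @export
read_patient_table <- function(path = cinegate_example("patient_table.csv")) {
  tbl <- utils::read.csv(path)
  need <- c("patient", "gtv_motion_cc", "v_lung_cc", "v_gtv_cc",
            "ratio_gtv_lung_1e4", "hepatic_dome_motion_cm")
  if (!all(need %in% names(tbl)))
    stopf("patient table needs columns %s", paste(need, collapse = ", "),
          class = "cinegate_format_error")
  if (any(tbl$v_lung_cc <= 0 | tbl$v_gtv_cc <= 0))
    stopf("volumes must be positive", class = "cinegate_format_error")
  tbl
}

#' Read a DVH-difference table
#'
#' @param path CSV with columns `structure`, `index`, `unit`, then one
#'   column of differences per patient. Defaults to the bundled
#'   margin-comparison table.
#' @return a data frame.
#' @export
read_dvh_table <- function(path = cinegate_example("dvh_table.csv")) {
  tbl <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("structure", "index") %in% names(tbl)))
    stopf("DVH table needs `structure` and `index` columns",
          class = "cinegate_format_error")
  tbl
}
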