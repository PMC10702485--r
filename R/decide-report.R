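#' Configuration of the gating-selection decision rule
#'
#' The decision layer applies a motion threshold to the simulation
#' free-breathing cine: when the centroid SD is strictly below 2 mm on
#' every examinable axis, free-breathing delivery with the narrow
#' MR-image-guided margin (MRIgM, 3 mm) is supported; otherwise
#' deep-inspiration breath-hold (also planned with a 3 mm margin) is
#' recommended. The 5 mm standard margin (SM) is carried along as the
#' legacy comparison margin for the DVH workflow.
#'
#' @param motion_threshold SD threshold in cm (default 0.2 = 2 mm).
#' @param fb_margin GTV-to-PTV margin for eligible FB patients (cm).
#' @param fb_margin_standard legacy FB margin for comparison (cm).
#' @param dibh_margin GTV-to-PTV margin for DIBH patients (cm).
#' @param metric `"sd"` (default; the centroid SD motion metric) or
#'   `"range"` if the caller supplies peak-to-peak amplitudes instead.
#' @return an object of class `decision_config`.
#' @export
decision_config <- function(motion_threshold = 0.2, fb_margin = 0.3,
                            fb_margin_standard = 0.5, dibh_margin = 0.3,
                            metric = c("sd", "range")) {
  metric <- match.arg(metric)
  for (nm in c("motion_threshold", "fb_margin", "fb_margin_standard",
               "dibh_margin"))
    assert_scalar_num(get(nm), nm, lower = 0, strict_lower = TRUE)
  if (fb_margin > fb_margin_standard)
    stopf("fb_margin must not exceed fb_margin_standard",
          class = "cinegate_invalid_argument")
  structure(list(motion_threshold = motion_threshold, fb_margin = fb_margin,
                 fb_margin_standard = fb_margin_standard,
                 dibh_margin = dibh_margin, metric = metric),
            class = "decision_config")
}

#' Recommend the gating technique for a patient
#'
#' Applies the motion criterion to the whole-cine summary of the
#' free-breathing simulation cine: free breathing is supported if and only
#' if the motion is strictly below the threshold on *both* examinable axes
#' (AP and CC); otherwise breath-hold gating is recommended. The
#' recommendation is decision support, not a clinical decision.
#'
#' @param sim_fb_summary a [motion_summary()] of the FB simulation cine
#'   (whole-cine scope; a DIP-only summary is rejected, because the
#'   criterion is defined on free-breathing motion).
#' @param cfg a [decision_config()].
#' @return a list of class `gating_recommendation`: `recommendation`
#'   (`"FB"` or `"DIBH"`), `margin` (cm), `rationale` (per-axis data
#'   frame), `config`.
#' @examples
#' recommend_gating(motion_summary(0.15, 0.10))  # FB, 0.3 cm margin
#' @export
recommend_gating <- function(sim_fb_summary, cfg = decision_config()) {
  stopifnot(inherits(sim_fb_summary, "motion_summary"),
            inherits(cfg, "decision_config"))
  if (identical(sim_fb_summary$scope, "dip_only"))
    stopf(paste("the FB eligibility criterion applies to free-breathing",
                "simulation motion, not to a DIP-only summary"),
          class = "cinegate_invalid_scope")
  sds <- c(ap = sim_fb_summary$sd_ap, cc = sim_fb_summary$sd_cc)
  below <- sds < cfg$motion_threshold
  fb <- all(below)
  rationale <- data.frame(axis = names(sds), sd_cm = unname(sds),
                          threshold_cm = cfg$motion_threshold,
                          below_threshold = unname(below))
  structure(list(recommendation = if (fb) "FB" else "DIBH",
                 margin = if (fb) cfg$fb_margin else cfg$dibh_margin,
                 rationale = rationale, config = cfg),
            class = "gating_recommendation")
}

#' @export
print.gating_recommendation <- function(x, ...) {
  cat(sprintf("<gating_recommendation> %s (GTV-to-PTV margin %.1f cm)\n",
              x$recommendation, x$margin))
  for (i in seq_len(nrow(x$rationale)))
    cat(sprintf("  %s: SD %.3f cm %s %.3f cm\n", x$rationale$axis[i],
                x$rationale$sd_cm[i],
                if (x$rationale$below_threshold[i]) "<" else ">=",
                x$rationale$threshold_cm[i]))
  invisible(x)
}

#' Pearson correlation with cohort-screen conventions
#'
#' Thin, validated wrapper around the sample Pearson correlation used for
#' the cohort screens: requires equal lengths of at least 3 and non-zero
#' variance on both sides, and carries the pair name and sample size in
#' the result (with the coefficient both at full precision and rounded to
#' the 2 decimals used in reports).
#'
#' @param x,y numeric vectors.
#' @param pair optional label.
#' @return a list of class `correlation_result`: `pair`, `r`, `r_rounded`,
#'   `n`.
#' @export
pearson_cor <- function(x, y, pair = NULL) {
  if (length(x) != length(y))
    stopf("x and y must have equal length", class = "cinegate_invalid_argument")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stopf("need at least 3 complete pairs", class = "cinegate_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance in %s",
          if (stats::sd(x) == 0) "x" else "y",
          class = "cinegate_undefined_correlation")
  r <- stats::cor(x, y)
  structure(list(pair = pair, r = r, r_rounded = round_half_up(r, 2),
                 n = length(x)),
            class = "correlation_result")
}

#' Screen GTV motion against anatomical surrogates
#'
#' Correlates the per-patient GTV cranio-caudal motion SD with (1) the GTV
#' volume, (2) the GTV-to-lung volume ratio and (3) the peak-to-peak
#' hepatic dome excursion — the candidate predictors a clinician could
#' read off the planning images before any cine is acquired.
#'
#' @param records data frame in the layout of [read_patient_table()]:
#'   columns `gtv_motion_cc`, `v_gtv_cc`, `ratio_gtv_lung_1e4`,
#'   `hepatic_dome_motion_cm`.
#' @return a data frame with one row per pair: `pair`, `r`, `r_rounded`,
#'   `n`.
#' @export
correlation_screen <- function(records) {
  need <- c("gtv_motion_cc", "v_gtv_cc", "ratio_gtv_lung_1e4",
            "hepatic_dome_motion_cm")
  if (!all(need %in% names(records)))
    stopf("records need columns %s", paste(need, collapse = ", "),
          class = "cinegate_format_error")
  pairs <- list(gtv_volume = "v_gtv_cc",
                gtv_lung_ratio = "ratio_gtv_lung_1e4",
                hepatic_dome_motion = "hepatic_dome_motion_cm")
  do.call(rbind, lapply(names(pairs), function(nm) {
    res <- pearson_cor(records$gtv_motion_cc, records[[pairs[[nm]]]],
                       pair = paste0("cc_motion~", nm))
    data.frame(pair = res$pair, r = res$r, r_rounded = res$r_rounded,
               n = res$n)
  }))
}

#' Check the printed volume-ratio column for self-consistency
#'
#' Recomputes `v_gtv / v_lung * 1e4` for every patient and compares it to
#' the stored ratio at the table's 2-decimal precision.
#'
#' @param records data frame with columns `v_gtv_cc`, `v_lung_cc`,
#'   `ratio_gtv_lung_1e4`.
#' @return the records with added columns `ratio_recomputed` and
#'   `ratio_consistent`.
#' @export
check_ratio <- function(records) {
  recomputed <- round_half_up(records$v_gtv_cc / records$v_lung_cc * 1e4, 2)
  records$ratio_recomputed <- recomputed
  records$ratio_consistent <-
    abs(recomputed - records$ratio_gtv_lung_1e4) < 0.005
  records
}

#' Aggregate per-patient DVH-index differences
#'
#' Mean of the per-patient differences for every (structure, DVH index)
#' row of a margin-comparison table (narrow minus standard margin, so
#' negative values are organ-at-risk dose reductions from the narrower
#' margin). Missing patient entries are skipped, with the count of values
#' used reported per row.
#'
#' @param records data frame in the layout of [read_dvh_table()]:
#'   `structure`, `index`, `unit`, then one column per patient.
#' @return the `structure`/`index`/`unit` columns plus `mean_diff` (full
#'   precision), `mean_diff_rounded` (2 decimals, report style) and
#'   `n_patients`.
#' @export
dvh_aggregate <- function(records) {
  meta <- intersect(c("structure", "index", "unit"), names(records))
  if (!all(c("structure", "index") %in% meta))
    stopf("records need `structure` and `index` columns",
          class = "cinegate_format_error")
  vals <- as.matrix(records[, setdiff(names(records), meta), drop = FALSE])
  if (ncol(vals) == 0L)
    stopf("no patient columns to aggregate", class = "cinegate_format_error")
  out <- records[, meta, drop = FALSE]
  out$mean_diff <- rowMeans(vals, na.rm = TRUE)
  out$mean_diff_rounded <- round_half_up(out$mean_diff, 2)
  out$n_patients <- rowSums(!is.na(vals))
  if (any(out$n_patients == 0L))
    stopf("row %d has no patient values", which(out$n_patients == 0L)[1],
          class = "cinegate_insufficient_data")
  out
}
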