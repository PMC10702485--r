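#' Motion summary container
#'
#' Per-cine motion expressed as the standard deviation of the GTV centroid
#' per axis — the quantitative motion metric of the workflow.
#'
#' @param sd_ap,sd_cc per-axis sample SD in cm.
#' @param n_frames_used number of valid frames entering the statistic.
#' @param n_invalid number of frames excluded by QC.
#' @param scope `"whole_cine"`, `"dip_only"` or `"fbp_only"`.
#' @return an object of class `motion_summary`.
#' @export
motion_summary <- function(sd_ap, sd_cc, n_frames_used = NA_integer_,
                           n_invalid = 0L, scope = "whole_cine") {
  if (any(c(sd_ap, sd_cc) < 0, na.rm = TRUE))
    stopf("SDs must be non-negative", class = "cinegate_invalid_argument")
  structure(list(sd_ap = sd_ap, sd_cc = sd_cc,
                 n_frames_used = n_frames_used, n_invalid = n_invalid,
                 scope = scope),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> SD AP %.3f cm, CC %.3f cm (%s, n = %s, %d invalid)\n",
              x$sd_ap, x$sd_cc, x$scope, x$n_frames_used, x$n_invalid))
  invisible(x)
}

#' Per-axis SD of a centroid trace
#'
#' Sample standard deviation (denominator n - 1) of the valid in-scope
#' centroid positions, per axis. Invalid frames are excluded and counted,
#' never interpolated.
#'
#' @param trace a `centroid_trace`.
#' @param scope_frames optional integer vector of frame numbers restricting
#'   the statistic (e.g. the frames of one breathing phase).
#' @param scope label stored in the result.
#' @return a [motion_summary()].
#' @examples
#' tr <- as_centroid_trace(
#'   generate_trace(motion_model("FB", amplitude_cc = 0.5), 60, 4))
#' motion_sd(tr)$sd_cc  # ~ 0.5 / sqrt(2) = 0.354
#' @export
motion_sd <- function(trace, scope_frames = NULL, scope = "whole_cine") {
  stopifnot(inherits(trace, "centroid_trace"))
  keep <- trace$valid
  if (!is.null(scope_frames)) keep <- keep & trace$frame %in% scope_frames
  n_inv <- sum(!trace$valid & (is.null(scope_frames) |
                                 trace$frame %in% scope_frames))
  if (sum(keep) < 2L)
    stopf("need at least 2 valid frames in scope to compute an SD",
          class = "cinegate_insufficient_data")
  motion_summary(sd_ap = stats::sd(trace$ap_cm[keep]),
                 sd_cc = stats::sd(trace$cc_cm[keep]),
                 n_frames_used = sum(keep), n_invalid = n_inv, scope = scope)
}

rolling_sd <- function(x, w) {
  n <- length(x)
  h1 <- floor((w - 1) / 2); h2 <- w - 1L - h1
  vapply(seq_len(n), function(i) {
    xi <- x[max(1L, i - h1):min(n, i + h2)]
    xi <- xi[!is.na(xi)]
    if (length(xi) < 2L) NA_real_ else stats::sd(xi)
  }, numeric(1))
}

#' Detect deep-inspiration breath-hold plateaus in a centroid trace
#'
#' Classifies every frame of a DIBH trace as deep-inspiration plateau
#' (`DIP`), free breathing (`FBP`) or `transition`. A frame is a plateau
#' candidate when its centered rolling-window SD is at most
#' `plateau_sd_max` and its level lies on the inspiration side of
#' `level_threshold`; candidate runs of at least `min_duration` are
#' accepted and then extended frame-by-frame while the signal stays within
#' `plateau_sd_max` of the run's median level (this recovers the plateau
#' edges that the rolling window blurs). A buffer of one window length on
#' each side of every plateau is labeled `transition`; everything else is
#' `FBP`.
#'
#' The detector works on the dominant axis (the one with the larger
#' whole-trace SD). `level_threshold = NULL` ("auto") uses the midpoint of
#' the 10th and 90th percentile levels; the inspiration side is then taken
#' as the side of the threshold whose frames are quieter (smaller median
#' rolling SD), since holds are quasi-static. A trace with no respiratory
#' modulation at all (level range below 1e-6 cm) is returned as a single
#' plateau spanning the whole trace, flagged in the QC notes.
#'
#' @param trace a `centroid_trace`.
#' @param window rolling-window length in s.
#' @param plateau_sd_max largest rolling SD (cm) accepted inside a hold.
#' @param min_duration shortest accepted hold (s).
#' @param level_threshold level (cm) separating inspiration from free
#'   breathing on the dominant axis, or `NULL` for automatic.
#' @param inspiration_side `"auto"`, `"above"` or `"below"` the threshold.
#' @return a `breath_segments` object: data frame of non-overlapping,
#'   ordered intervals (`start_frame`, `end_frame`, `label`) covering all
#'   frames, with the detector parameters and QC notes as attributes.
#' @export
detect_breath_holds <- function(trace, window = 2, plateau_sd_max = 0.1,
                                min_duration = 3, level_threshold = NULL,
                                inspiration_side = c("auto", "above", "below")) {
  stopifnot(inherits(trace, "centroid_trace"))
  inspiration_side <- match.arg(inspiration_side)
  fr <- attr(trace, "frame_rate")
  n <- nrow(trace)
  if (n / fr < min_duration)
    stopf("trace shorter than min_duration",
          class = "cinegate_insufficient_data")
  params <- list(window = window, plateau_sd_max = plateau_sd_max,
                 min_duration = min_duration,
                 level_threshold = level_threshold,
                 inspiration_side = inspiration_side)
  qc <- character(0)

  sds <- c(ap = stats::sd(trace$ap_cm[trace$valid]),
           cc = stats::sd(trace$cc_cm[trace$valid]))
  axis <- if (sds[["cc"]] >= sds[["ap"]]) "cc_cm" else "ap_cm"
  x <- ifelse(trace$valid, trace[[axis]], NA_real_)
  w <- max(2L, round(window * fr))

  q <- stats::quantile(x, c(0.1, 0.9), na.rm = TRUE, names = FALSE)
  if (diff(q) < 1e-6) {
    qc <- c(qc, "no respiratory modulation; whole trace treated as one plateau")
    seg <- data.frame(start_frame = 1L, end_frame = n, label = "DIP")
    return(structure(seg, class = c("breath_segments", "data.frame"),
                     params = params, axis = axis, qc_notes = qc))
  }
  thr <- if (is.null(level_threshold)) mean(q) else level_threshold
  rsd <- rolling_sd(x, w)

  side_above <- !is.na(x) & x > thr
  side_below <- !is.na(x) & x <= thr
  if (inspiration_side == "auto") {
    med_a <- stats::median(rsd[side_above], na.rm = TRUE)
    med_b <- stats::median(rsd[side_below], na.rm = TRUE)
    inspiration_side <- if (isTRUE(med_a <= med_b) || !any(side_below))
      "above" else "below"
    params$inspiration_side_resolved <- inspiration_side
  }
  on_side <- if (inspiration_side == "above") side_above else side_below

  cand <- !is.na(rsd) & rsd <= plateau_sd_max & on_side
  min_frames <- max(2L, ceiling(min_duration * fr))
  is_dip <- logical(n)
  runs <- true_runs(cand)
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, "start"]; e <- runs[r, "end"]
    if (e - s + 1L < min_frames) next
    level <- stats::median(x[s:e], na.rm = TRUE)
    while (s > 1L && !is.na(x[s - 1L]) &&
           abs(x[s - 1L] - level) <= plateau_sd_max) s <- s - 1L
    while (e < n && !is.na(x[e + 1L]) &&
           abs(x[e + 1L] - level) <= plateau_sd_max) e <- e + 1L
    is_dip[s:e] <- TRUE
  }

  label <- rep("FBP", n)
  label[is_dip] <- "DIP"
  dip_runs <- true_runs(is_dip)
  for (r in seq_len(nrow(dip_runs))) {
    s <- dip_runs[r, "start"]; e <- dip_runs[r, "end"]
    pre <- seq(max(1L, s - w), s - 1L)
    post <- seq(e + 1L, min(n, e + w))
    if (s > 1L) label[pre[label[pre] == "FBP"]] <- "transition"
    if (e < n) label[post[label[post] == "FBP"]] <- "transition"
  }
  r <- rle(label)
  ends <- cumsum(r$lengths)
  seg <- data.frame(start_frame = ends - r$lengths + 1L,
                    end_frame = ends, label = r$values)
  structure(seg, class = c("breath_segments", "data.frame"),
            params = params, axis = axis, qc_notes = qc)
}

## frame numbers carrying a given label
segment_frames <- function(segments, label = "DIP") {
  sel <- segments$label == label
  if (!any(sel)) return(integer(0))
  unlist(Map(seq.int, segments$start_frame[sel], segments$end_frame[sel]))
}

#' Within-plateau motion of a breath-hold trace
#'
#' Motion SD restricted to the deep-inspiration plateaus. Two pooling
#' conventions are available:
#'
#' * `"per_plateau_pooled"` (default): deviations are taken from each
#'   plateau's own mean and pooled, with denominator `n - k` for `k`
#'   plateaus — this removes inter-hold baseline offsets, which reflect
#'   how reproducibly the patient returns to inspiration rather than
#'   intra-hold target motion.
#' * `"global"`: one sample SD over all concatenated plateau frames about
#'   their common mean (denominator `n - 1`), which folds the hold-to-hold
#'   level differences into the result.
#'
#' @param trace a `centroid_trace`.
#' @param segments a `breath_segments` from [detect_breath_holds()].
#' @param pooling `"per_plateau_pooled"` or `"global"`.
#' @return a [motion_summary()] with scope `"dip_only"`.
#' @export
dip_motion_sd <- function(trace, segments,
                          pooling = c("per_plateau_pooled", "global")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(trace, "centroid_trace"),
            inherits(segments, "breath_segments"))
  sel <- segments$label == "DIP"
  if (!any(sel))
    stopf("no DIP intervals in the segmentation",
          class = "cinegate_insufficient_data")
  plateaus <- Map(seq.int, segments$start_frame[sel], segments$end_frame[sel])
  one_axis <- function(col) {
    vals <- lapply(plateaus, function(fr) {
      v <- trace[[col]][trace$frame %in% fr & trace$valid]
      v[!is.na(v)]
    })
    vals <- vals[lengths(vals) > 0L]
    nn <- sum(lengths(vals))
    if (pooling == "global") {
      all <- unlist(vals)
      if (length(all) < 2L)
        stopf("fewer than 2 valid DIP frames",
              class = "cinegate_insufficient_data")
      stats::sd(all)
    } else {
      k <- length(vals)
      if (nn - k < 1L)
        stopf("not enough DIP frames for pooled SD (n = %d, k = %d)", nn, k,
              class = "cinegate_insufficient_data")
      ss <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
      sqrt(ss / (nn - k))
    }
  }
  n_used <- sum(trace$frame %in% unlist(plateaus) & trace$valid)
  n_inv <- sum(trace$frame %in% unlist(plateaus) & !trace$valid)
  motion_summary(sd_ap = one_axis("ap_cm"), sd_cc = one_axis("cc_cm"),
                 n_frames_used = n_used, n_invalid = n_inv,
                 scope = "dip_only")
}

#' Patient-level motion summary
#'
#' Combines the simulation cine with the per-fraction treatment cines of
#' one patient: per axis, the mean, minimum and maximum of the fraction
#' SDs, alongside the simulation SD. `as.data.frame()` renders the
#' clinical-report row (values rounded to 0.01 cm); the object itself
#' keeps full precision.
#'
#' @param sim a [motion_summary()] from the simulation cine.
#' @param fractions non-empty list of [motion_summary()], one per treated
#'   fraction.
#' @param patient_id optional identifier.
#' @return a `patient_motion_summary`.
#' @export
summarize_patient <- function(sim, fractions, patient_id = NULL) {
  stopifnot(inherits(sim, "motion_summary"))
  if (!is.list(fractions) || length(fractions) == 0L ||
      !all(vapply(fractions, inherits, logical(1), "motion_summary")))
    stopf("`fractions` must be a non-empty list of motion summaries",
          class = "cinegate_invalid_argument")
  ap <- vapply(fractions, `[[`, numeric(1), "sd_ap")
  cc <- vapply(fractions, `[[`, numeric(1), "sd_cc")
  patient_motion_summary(
    patient_id = patient_id,
    sim = c(ap = sim$sd_ap, cc = sim$sd_cc),
    mean = c(ap = mean(ap), cc = mean(cc)),
    min = c(ap = min(ap), cc = min(cc)),
    max = c(ap = max(ap), cc = max(cc)),
    per_fraction = fractions)
}

#' @param sim,mean,min,max named numeric `c(ap = , cc = )` SDs in cm.
#' @param per_fraction optional list of per-fraction [motion_summary()]s
#'   (absent when the summary is built from an already-aggregated table).
#' @param gating optional `"FB"` or `"DIBH"` label.
#' @rdname summarize_patient
#' @export
patient_motion_summary <- function(patient_id, sim, mean, min, max,
                                   per_fraction = NULL, gating = NULL) {
  for (axis in c("ap", "cc"))
    if (!(min[[axis]] <= mean[[axis]] && mean[[axis]] <= max[[axis]] +
          sqrt(.Machine$double.eps)))
      stopf("min <= mean <= max violated on %s axis", axis,
            class = "cinegate_invalid_argument")
  structure(list(patient_id = patient_id, sim = sim, mean = mean,
                 min = min, max = max, per_fraction = per_fraction,
                 gating = gating),
            class = "patient_motion_summary")
}

#' @export
as.data.frame.patient_motion_summary <- function(x, ...) {
  r2 <- function(v) round_half_up(v, 2)
  data.frame(patient = if (is.null(x$patient_id)) NA else x$patient_id,
             sim_ap = r2(x$sim[["ap"]]), mean_ap = r2(x$mean[["ap"]]),
             min_ap = r2(x$min[["ap"]]), max_ap = r2(x$max[["ap"]]),
             sim_cc = r2(x$sim[["cc"]]), mean_cc = r2(x$mean[["cc"]]),
             min_cc = r2(x$min[["cc"]]), max_cc = r2(x$max[["cc"]]))
}

#' Is the simulation motion representative of treatment?
#'
#' Flags, per axis, whether the simulation SD falls inside the range of
#' SDs observed over the treatment fractions (inclusive, optionally padded
#' by `tolerance`). Across the study cohort this check holds for every
#' patient, which is what justifies choosing the gating technique from the
#' simulation cine alone.
#'
#' @param p a `patient_motion_summary`.
#' @param tolerance padding in cm added to both ends of the range.
#' @return data frame with one row per axis: `axis`, `sim_sd`, `min_sd`,
#'   `max_sd`, `consistent`, `excess` (how far outside the padded range
#'   the simulation value lies; 0 when consistent).
#' @export
sim_vs_treatment <- function(p, tolerance = 0) {
  stopifnot(inherits(p, "patient_motion_summary"))
  out <- do.call(rbind, lapply(c("ap", "cc"), function(axis) {
    s <- p$sim[[axis]]; lo <- p$min[[axis]] - tolerance
    hi <- p$max[[axis]] + tolerance
    data.frame(axis = axis, sim_sd = s, min_sd = p$min[[axis]],
               max_sd = p$max[[axis]],
               consistent = s >= lo & s <= hi,
               excess = pmax(0, lo - s, s - hi))
  }))
  attr(out, "patient_id") <- p$patient_id
  out
}

#' Extrema of motion statistics over a cohort
#'
#' Range (min, max) of selected per-patient SD statistics over a list of
#' patient summaries — e.g. the extremes of all per-fraction SDs over all
#' free-breathing patients and both axes.
#'
#' @param summaries list of `patient_motion_summary`.
#' @param fields which statistics to pool: any of `"sim"`, `"mean"`,
#'   `"min"`, `"max"`.
#' @param axes which axes to pool: `"ap"`, `"cc"` or both.
#' @return named numeric `c(min = , max = )` in cm.
#' @export
cohort_range <- function(summaries, fields = c("min", "max"),
                         axes = c("ap", "cc")) {
  if (!is.list(summaries) || length(summaries) == 0L ||
      !all(vapply(summaries, inherits, logical(1), "patient_motion_summary")))
    stopf("`summaries` must be a non-empty list of patient summaries",
          class = "cinegate_invalid_argument")
  fields <- match.arg(fields, c("sim", "mean", "min", "max"),
                      several.ok = TRUE)
  axes <- match.arg(axes, c("ap", "cc"), several.ok = TRUE)
  vals <- unlist(lapply(summaries, function(s)
    unlist(lapply(fields, function(f) s[[f]][axes]))))
  c(min = min(vals), max = max(vals))
}

#' Simulate the beam-gating rule over segmented cine frames
#'
#' For every frame, the fraction of the GTV region lying outside the
#' gating boundary region; the beam is on while that fraction does not
#' exceed `threshold` (inclusive — delivery stops only when *more* than
#' the threshold fraction is outside, 5% by default). Frames with an empty
#' GTV region are excluded from the duty cycle and listed in the result's
#' attributes.
#'
#' The gating boundary never moves during a cine, but its yellow contour
#' can be partially overdrawn by the red GTV contour on frames where the
#' lesion approaches it, leaving the boundary unfillable on exactly the
#' frames that matter most. `static_boundary = TRUE` therefore replaces
#' every frame's boundary region with the per-pixel majority vote over the
#' frames whose boundary segmentation succeeded. [gate_cine()] enables
#' this by default; the per-frame primitive keeps it off so constructed
#' mask sequences are evaluated exactly as given (frames whose boundary
#' failed QC are then excluded like empty-GTV frames).
#'
#' @param masks list of `overlay_masks` (one per frame), e.g. from
#'   [segment_overlay()] applied over a stack.
#' @param threshold largest tolerated outside fraction (default 0.05).
#' @param static_boundary use a consensus boundary across frames (see
#'   Details).
#' @return a `gating_result` data frame (`frame`, `fraction_outside`,
#'   `beam_on`) with attributes `duty_cycle`, `threshold` and
#'   `excluded_frames`.
#' @export
gating_trace <- function(masks, threshold = 0.05, static_boundary = FALSE) {
  if (!is.list(masks) || length(masks) == 0L ||
      !all(vapply(masks, inherits, logical(1), "overlay_masks")))
    stopf("`masks` must be a non-empty list of overlay_masks",
          class = "cinegate_invalid_argument")
  assert_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  bvalid <- vapply(masks, function(m)
    is.null(m$boundary_valid) || isTRUE(m$boundary_valid), logical(1))
  consensus <- NULL
  if (static_boundary) {
    if (!any(bvalid))
      stopf("boundary segmentation failed on every frame",
            class = "cinegate_tracking_failure")
    votes <- Reduce(`+`, lapply(masks[bvalid],
                                function(m) m$boundary_region_mask * 1L))
    consensus <- votes > sum(bvalid) / 2
  }
  frac <- vapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    ngtv <- sum(m$gtv_region_mask)
    if (ngtv == 0L) return(NA_real_)
    if (!static_boundary && !bvalid[i]) return(NA_real_)
    boundary <- if (static_boundary) consensus else m$boundary_region_mask
    sum(m$gtv_region_mask & !boundary) / ngtv
  }, numeric(1))
  beam_on <- frac <= threshold
  out <- data.frame(frame = seq_along(masks), fraction_outside = frac,
                    beam_on = beam_on)
  structure(out, class = c("gating_result", "data.frame"),
            duty_cycle = mean(beam_on[!is.na(frac)]),
            threshold = threshold,
            excluded_frames = which(is.na(frac)))
}

#' @param stack a `frame_stack`.
#' @param spec a [color_spec()].
#' @rdname gating_trace
#' @export
gate_cine <- function(stack, spec = color_spec(), threshold = 0.05,
                      static_boundary = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  gating_trace(lapply(stack$frames, segment_overlay, spec = spec),
               threshold = threshold, static_boundary = static_boundary)
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %d frames, duty cycle %.1f%% (threshold %.0f%%)\n",
              nrow(x), 100 * attr(x, "duty_cycle"),
              100 * attr(x, "threshold")))
  invisible(x)
}
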