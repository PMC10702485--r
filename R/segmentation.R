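#' RGB threshold rules for the tracking overlays
#'
#' The exported cine is grayscale anatomy with only two colored overlays:
#' the red GTV contour and the yellow gating boundary. Both are isolated by
#' per-channel inclusive thresholds; the defaults tolerate substantial
#' chroma error from lossy video compression while keeping the two rules
#' mutually exclusive (red requires low green, yellow requires high green).
#'
#' @param red named numeric `c(r_lo, g_hi, b_hi)`: a pixel is red when
#'   `R >= r_lo & G <= g_hi & B <= b_hi`.
#' @param yellow named numeric `c(r_lo, g_lo, b_hi)`: a pixel is yellow
#'   when `R >= r_lo & G >= g_lo & B <= b_hi`.
#' @return an object of class `color_spec`.
#' @export
color_spec <- function(red = c(r_lo = 180, g_hi = 100, b_hi = 100),
                       yellow = c(r_lo = 180, g_lo = 180, b_hi = 100)) {
  stopifnot(length(red) == 3L, length(yellow) == 3L)
  red <- stats::setNames(as.numeric(red), c("r_lo", "g_hi", "b_hi"))
  yellow <- stats::setNames(as.numeric(yellow), c("r_lo", "g_lo", "b_hi"))
  if (yellow[["g_lo"]] <= red[["g_hi"]])
    stopf("red and yellow rules overlap: yellow g_lo must exceed red g_hi",
          class = "cinegate_invalid_argument")
  structure(list(red = red, yellow = yellow), class = "color_spec")
}

## threshold -> largest connected component -> 3x3 closing; returns the
## contour mask, its filled region, and QC facts
extract_overlay <- function(mask_cand, min_pixels) {
  note <- character(0)
  if (!any(mask_cand)) {
    empty <- matrix(FALSE, nrow(mask_cand), ncol(mask_cand))
    return(list(contour = empty, region = empty, valid = FALSE,
                notes = "no pixels matched the color rule"))
  }
  lab <- EBImage::bwlabel(mask_cand * 1L)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- lab == keep
  if (counts[keep] < min_pixels)
    note <- c(note, sprintf("largest component has %d px (< %d)",
                            counts[keep], min_pixels))
  closed <- erode3(dilate3(comp))
  closed <- closed | comp            # closing never removes the component
  region <- EBImage::fillHull(closed * 1L) > 0
  # a closed contour yields a region with interior; an open arc does not
  has_interior <- any(erode3(region))
  if (!has_interior)
    note <- c(note, "contour could not be closed into a region")
  list(contour = closed, region = region,
       valid = counts[keep] >= min_pixels && has_interior,
       notes = note)
}

#' Segment the tracking overlays on one cine frame
#'
#' Applies the red and yellow threshold rules pixel-wise, keeps the largest
#' connected component of each, closes it morphologically (3 x 3), and
#' fills the closed contour to obtain the corresponding region. Degenerate
#' frames (too few red pixels, unclosable contour) are flagged via
#' `valid = FALSE` and `qc_notes`, never raised as errors, so a few bad
#' frames do not abort a whole cine.
#'
#' @param frame a `rows x cols x 3` 8-bit RGB array.
#' @param spec a [color_spec()].
#' @param min_pixels smallest GTV component accepted as a valid detection.
#' @return an `overlay_masks` object: logical matrices
#'   `gtv_contour_mask`, `gtv_region_mask`, `boundary_contour_mask`,
#'   `boundary_region_mask`, plus `valid` and `qc_notes`.
#' @export
segment_overlay <- function(frame, spec = color_spec(), min_pixels = 8L) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stopf("frame must be a rows x cols x 3 RGB array",
          class = "cinegate_invalid_argument")
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  red_cand <- R >= spec$red[["r_lo"]] & G <= spec$red[["g_hi"]] &
    B <= spec$red[["b_hi"]]
  yel_cand <- R >= spec$yellow[["r_lo"]] & G >= spec$yellow[["g_lo"]] &
    B <= spec$yellow[["b_hi"]]
  gtv <- extract_overlay(red_cand, min_pixels)
  bnd <- extract_overlay(yel_cand, min_pixels)
  notes <- c(if (length(gtv$notes)) paste("GTV:", gtv$notes),
             if (length(bnd$notes)) paste("boundary:", bnd$notes))
  structure(list(gtv_contour_mask = gtv$contour,
                 gtv_region_mask = gtv$region,
                 boundary_contour_mask = bnd$contour,
                 boundary_region_mask = bnd$region,
                 valid = gtv$valid,
                 boundary_valid = bnd$valid,
                 qc_notes = notes),
            class = "overlay_masks")
}

#' Centroid of a binary mask in patient coordinates
#'
#' The arithmetic mean of the centers of the set pixels, scaled to cm.
#' Pixel `(r, c)` (1-based) covers `[(r-1), r) x [(c-1), c)` in pixel
#' units, so its center contributes `(c - 0.5) * col_spacing` to AP and
#' `(r - 0.5) * row_spacing` to CC. This half-pixel convention shifts all
#' absolute positions identically and therefore leaves motion SDs
#' untouched.
#'
#' @param mask logical (or 0/1) matrix.
#' @param spacing `(row, col)` spacing in cm/pixel.
#' @return named numeric `c(ap = , cc = )` in cm.
#' @export
mask_centroid <- function(mask, spacing = c(0.35, 0.35)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stopf("cannot take the centroid of an empty mask",
          class = "cinegate_empty_mask")
  c(ap = mean((idx[, 2] - 0.5) * spacing[2]),
    cc = mean((idx[, 1] - 0.5) * spacing[1]))
}

#' Track the GTV centroid through a cine
#'
#' Runs [segment_overlay()] on every frame and measures the GTV centroid,
#' producing the centroid time series the motion statistics operate on.
#' Frames whose GTV detection fails QC get `valid = FALSE` and `NA`
#' positions; they are excluded (never interpolated) downstream.
#'
#' @param stack a `frame_stack`.
#' @param spec a [color_spec()].
#' @param mode `"region"` (default; centroid of the filled contour, less
#'   sensitive to contour-thickness asymmetry) or `"contour"` (centroid of
#'   the outline pixels only, kept for sensitivity analysis).
#' @param min_pixels passed to [segment_overlay()].
#' @param cine_id,session optional identifiers carried into summaries.
#' @return a `centroid_trace`: data frame with columns `frame`, `t_s`,
#'   `ap_cm`, `cc_cm`, `valid`; attributes `frame_rate`, `pixel_spacing`,
#'   `cine_id`, `session`.
#' @export
track_cine <- function(stack, spec = color_spec(),
                       mode = c("region", "contour"), min_pixels = 8L,
                       cine_id = NULL, session = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  ap <- cc <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    m <- segment_overlay(stack$frames[[i]], spec, min_pixels)
    if (m$valid) {
      mk <- if (mode == "region") m$gtv_region_mask else m$gtv_contour_mask
      pos <- mask_centroid(mk, stack$pixel_spacing)
      ap[i] <- pos[["ap"]]; cc[i] <- pos[["cc"]]
      valid[i] <- TRUE
    }
  }
  if (!any(valid))
    stopf("GTV tracking failed on every frame",
          class = "cinegate_tracking_failure")
  centroid_trace(data.frame(frame = seq_len(n),
                            t_s = (seq_len(n) - 1L) / stack$frame_rate,
                            ap_cm = ap, cc_cm = cc, valid = valid),
                 frame_rate = stack$frame_rate,
                 pixel_spacing = stack$pixel_spacing,
                 cine_id = cine_id, session = session)
}

#' Centroid trace container
#'
#' @param df data frame with columns `frame`, `t_s`, `ap_cm`, `cc_cm` and
#'   optionally `valid` (defaults to `TRUE` where positions are present).
#' @param frame_rate frames per second.
#' @param pixel_spacing optional `(row, col)` cm/pixel provenance.
#' @param cine_id,session optional identifiers (`session` is typically
#'   `"simulation"` or `"fraction_k"`).
#' @return a `centroid_trace` data frame.
#' @export
centroid_trace <- function(df, frame_rate = 4, pixel_spacing = NULL,
                           cine_id = NULL, session = NULL) {
  need <- c("frame", "t_s", "ap_cm", "cc_cm")
  if (!all(need %in% names(df)))
    stopf("trace needs columns %s", paste(need, collapse = ", "),
          class = "cinegate_format_error")
  if (is.null(df$valid)) df$valid <- !is.na(df$ap_cm) & !is.na(df$cc_cm)
  if (is.unsorted(df$t_s, strictly = TRUE))
    stopf("trace times must be strictly increasing",
          class = "cinegate_format_error")
  structure(df, class = c("centroid_trace", "data.frame"),
            frame_rate = frame_rate, pixel_spacing = pixel_spacing,
            cine_id = cine_id, session = session)
}

#' Convert a ground-truth trace to a centroid trace
#'
#' Lets the motion-analysis operations run directly on generator output,
#' e.g. to compare tracked against true motion.
#'
#' @param truth a `ground_truth` from [generate_trace()].
#' @param cine_id,session optional identifiers.
#' @return a `centroid_trace`.
#' @export
as_centroid_trace <- function(truth, cine_id = NULL, session = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  centroid_trace(data.frame(frame = truth$frame, t_s = truth$t_s,
                            ap_cm = truth$ap_cm, cc_cm = truth$cc_cm,
                            valid = TRUE),
                 frame_rate = attr(truth, "frame_rate"),
                 cine_id = cine_id, session = session)
}

#' Write / read a centroid trace as CSV
#'
#' The on-disk format is the five-column CSV (`frame`, `t_s`, `ap_cm`,
#' `cc_cm`, `valid`) used to exchange traces between the tracking and
#' analysis stages.
#'
#' @param trace a `centroid_trace`.
#' @param path CSV file path.
#' @param frame_rate frames per second of the stored trace (read only).
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   `centroid_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "centroid_trace"))
  utils::write.csv(as.data.frame(trace)[, c("frame", "t_s", "ap_cm",
                                            "cc_cm", "valid")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, frame_rate = 4) {
  if (!file.exists(path))
    stopf("trace file '%s' not found", path, class = "cinegate_io_error")
  centroid_trace(utils::read.csv(path), frame_rate = frame_rate,
                 cine_id = tools::file_path_sans_ext(basename(path)))
}
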