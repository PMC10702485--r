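# Independent oracles and small fixture builders used across the suite.

# brute-force pixel-mean centroid: explicit loop over set pixels,
# independent of the vectorised implementation under test
oracle_centroid <- function(mask, spacing) {
  ap <- 0; cc <- 0; n <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c]) {
      ap <- ap + (c - 0.5) * spacing[2]
      cc <- cc + (r - 0.5) * spacing[1]
      n <- n + 1
    }
  }
  c(ap = ap / n, cc = cc / n)
}

# Pearson r from the covariance definition, written independently of cor()
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# a small rendered FB cine with its ground truth
make_fb_cine <- function(amplitude_ap = 0.1, amplitude_cc = 0.15,
                         duration = 20, seed = 1, period = 4,
                         noise = "off", les = lesion_spec(),
                         cfg = render_config(compression_noise = noise,
                                             seed = seed)) {
  truth <- generate_trace(
    motion_model("FB", amplitude_ap = amplitude_ap,
                 amplitude_cc = amplitude_cc, period = period),
    duration = duration, frame_rate = cfg$frame_rate, seed = seed,
    rest_center = les$rest_center)
  list(truth = truth, lesion = les, cfg = cfg,
       stack = render_frames(truth, les, cfg = cfg))
}

# hand-built overlay_masks with an exact number of GTV pixels outside the
# boundary, for pixel-counted gating checks
make_gating_masks <- function(n_gtv, n_outside, dim = c(30, 30)) {
  gtv <- matrix(FALSE, dim[1], dim[2])
  gtv[cbind(5 + (seq_len(n_gtv) - 1) %/% dim[2],
            1 + (seq_len(n_gtv) - 1) %% dim[2])] <- TRUE
  boundary <- matrix(TRUE, dim[1], dim[2])
  if (n_outside > 0) {
    idx <- which(gtv, arr.ind = TRUE)[seq_len(n_outside), , drop = FALSE]
    boundary[idx] <- FALSE
  }
  structure(list(gtv_contour_mask = gtv, gtv_region_mask = gtv,
                 boundary_contour_mask = boundary,
                 boundary_region_mask = boundary,
                 valid = TRUE, qc_notes = character(0)),
            class = "overlay_masks")
}

# manual breath segmentation (bypasses the detector) for statistics tests
manual_segments <- function(starts, ends, labels) {
  structure(data.frame(start_frame = starts, end_frame = ends,
                       label = labels),
            class = c("breath_segments", "data.frame"),
            params = list(), axis = "cc_cm", qc_notes = character(0))
}

# frames of a detector segmentation labelled DIP
dip_frames_of <- function(seg) {
  sel <- seg$label == "DIP"
  if (!any(sel)) return(integer(0))
  unlist(Map(seq.int, seg$start_frame[sel], seg$end_frame[sel]))
}
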