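flat_trace <- function(ap, cc, frame_rate = 4) {
  n <- length(ap)
  centroid_trace(data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / frame_rate,
                            ap_cm = ap, cc_cm = cc, valid = TRUE),
                 frame_rate = frame_rate)
}

test_that("motion_sd computes the sample SD over valid frames", {
  tr <- flat_trace(rep(1.2, 10), rep(3.4, 10))
  s <- motion_sd(tr)
  expect_equal(c(s$sd_ap, s$sd_cc), c(0, 0))

  s2 <- motion_sd(flat_trace(c(0, 0.2), c(0, 0.2)))
  expect_equal(s2$sd_ap, 0.1414214, tolerance = 1e-6)   # n-1 denominator

  # invalid frames are excluded and counted, not interpolated
  tr3 <- flat_trace(c(0, 0.2, 99, 0.1), c(0, 0.2, 99, 0.1))
  tr3$valid[3] <- FALSE; tr3$ap_cm[3] <- NA; tr3$cc_cm[3] <- NA
  s3 <- motion_sd(tr3)
  expect_equal(s3$n_frames_used, 3L)
  expect_equal(s3$n_invalid, 1L)
  expect_equal(s3$sd_ap, sd(c(0, 0.2, 0.1)))

  expect_error(motion_sd(flat_trace(1, 1)),
               class = "cinegate_insufficient_data")
})

test_that("motion SD is shift-invariant and scale-equivariant", {
  set.seed(3)
  for (k in 1:5) {
    ap <- rnorm(50); cc <- rnorm(50)
    s0 <- motion_sd(flat_trace(ap, cc))
    s_shift <- motion_sd(flat_trace(ap + 2.7, cc - 1.1))
    s_scale <- motion_sd(flat_trace(3 * ap, 3 * cc))
    expect_equal(s_shift$sd_ap, s0$sd_ap, tolerance = 1e-12)
    expect_equal(s_shift$sd_cc, s0$sd_cc, tolerance = 1e-12)
    expect_equal(s_scale$sd_ap, 3 * s0$sd_ap, tolerance = 1e-12)
  }
})

test_that("tracked sinusoidal motion reproduces the A/sqrt(2) law sub-pixel", {
  # 60 s noise-free cine at 0.35 cm pixels: the area centroid resolves
  # motion well below the pixel size
  cine <- make_fb_cine(amplitude_ap = 0.25, amplitude_cc = 0.5,
                       duration = 60, seed = 4)
  s <- motion_sd(track_cine(cine$stack))
  truth_sd_ap <- sd(cine$truth$ap_cm)
  truth_sd_cc <- sd(cine$truth$cc_cm)
  expect_lt(abs(s$sd_ap - truth_sd_ap), 0.02)
  expect_lt(abs(s$sd_cc - truth_sd_cc), 0.02)
  expect_lt(abs(s$sd_cc - 0.5 / sqrt(2)), 0.02)
})

test_that("the plateau detector recovers noise-free breath-holds exactly", {
  m <- motion_model("DIBH", amplitude_ap = 0.4, amplitude_cc = 0.6,
                    plateau_duration = 15, n_holds = 6,
                    inter_hold_fb_duration = 5, intra_hold_jitter_sd = 0)
  tr <- generate_trace(m, 130, 4, seed = 7)
  seg <- detect_breath_holds(as_centroid_trace(tr))
  dip <- seg[seg$label == "DIP", ]
  expect_equal(nrow(dip), 6L)
  r <- rle(tr$label == "DIP"); e <- cumsum(r$lengths)
  truth_runs <- cbind(e - r$lengths + 1L, e)[r$values, , drop = FALSE]
  expect_true(all(abs(dip$start_frame - truth_runs[, 1]) <= 1))
  expect_true(all(abs(dip$end_frame - truth_runs[, 2]) <= 1))
  # intervals ordered, non-overlapping, covering every frame
  expect_true(all(seg$start_frame <= seg$end_frame))
  expect_equal(seg$start_frame[-1], seg$end_frame[-nrow(seg)] + 1L)
  expect_equal(seg$start_frame[1], 1L)
  expect_equal(seg$end_frame[nrow(seg)], nrow(tr))
})

test_that("pure breathing yields no plateaus; a flat trace is one plateau", {
  sin_tr <- as_centroid_trace(
    generate_trace(motion_model("FB", amplitude_ap = 0.5, amplitude_cc = 1,
                                period = 4), 60, 4))
  seg <- detect_breath_holds(sin_tr)
  expect_equal(sum(seg$label == "DIP"), 0L)

  const <- flat_trace(rep(2, 80), rep(5, 80))
  seg2 <- detect_breath_holds(const)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$label, "DIP")
  expect_equal(c(seg2$start_frame, seg2$end_frame), c(1L, 80L))
  expect_match(paste(attr(seg2, "qc_notes"), collapse = " "),
               "no respiratory modulation")
})

test_that("pooled and global DIP statistics differ exactly as intended", {
  # single plateau: both pooling modes agree
  tr <- flat_trace(rnorm(40, sd = 0.05), rnorm(40, sd = 0.05))
  seg1 <- manual_segments(1L, 40L, "DIP")
  expect_equal(dip_motion_sd(tr, seg1, "per_plateau_pooled")$sd_cc,
               dip_motion_sd(tr, seg1, "global")$sd_cc, tolerance = 1e-12)

  # two internally constant plateaus at 3.0 and 3.4 cm: within-plateau
  # SD is 0; the global SD about the common mean tends to 0.2 cm
  n <- 200
  tr2 <- flat_trace(c(rep(3.0, n), rep(3.4, n)), c(rep(3.0, n), rep(3.4, n)))
  seg2 <- manual_segments(c(1L, n + 1L), c(n, 2L * n), c("DIP", "DIP"))
  expect_equal(dip_motion_sd(tr2, seg2, "per_plateau_pooled")$sd_cc, 0)
  expect_lt(abs(dip_motion_sd(tr2, seg2, "global")$sd_cc - 0.2), 1e-3)

  # detected holds recover the generating intra-hold jitter
  m <- motion_model("DIBH", amplitude_ap = 0.4, amplitude_cc = 0.6,
                    intra_hold_jitter_sd = 0.05)
  tr3 <- as_centroid_trace(generate_trace(m, 130, 4, seed = 21))
  s <- dip_motion_sd(tr3, detect_breath_holds(tr3))
  expect_lt(abs(s$sd_ap - 0.05), 0.01)
  expect_lt(abs(s$sd_cc - 0.05), 0.01)
  expect_equal(s$scope, "dip_only")
})

test_that("pooled within-plateau SD never exceeds the global SD across baseline shifts", {
  set.seed(9)
  for (k in 1:10) {
    n_holds <- sample(2:5, 1)
    levels <- cumsum(c(3, runif(n_holds - 1, 0.1, 0.5)))
    lens <- sample(20:40, n_holds, replace = TRUE)
    vals <- unlist(Map(function(l, m) rnorm(l, mean = m, sd = 0.05),
                       lens, levels))
    ends <- cumsum(lens); starts <- ends - lens + 1L
    tr <- flat_trace(vals, vals)
    seg <- manual_segments(starts, ends, rep("DIP", n_holds))
    expect_lte(dip_motion_sd(tr, seg, "per_plateau_pooled")$sd_cc,
               dip_motion_sd(tr, seg, "global")$sd_cc)
  }
})

test_that("patient summaries aggregate fractions in report shape", {
  ms <- function(ap, cc) motion_summary(ap, cc)
  fracs <- list(ms(0.06, 0.07), ms(0.09, 0.12), ms(0.11, 0.09))
  p <- summarize_patient(ms(0.06, 0.11), fracs, patient_id = 1)
  row <- as.data.frame(p)
  expect_equal(row$mean_ap, 0.09)     # rounded to 0.01 cm for reports
  expect_equal(row$min_ap, 0.06)
  expect_equal(row$max_ap, 0.11)
  expect_equal(p$mean[["ap"]], mean(c(0.06, 0.09, 0.11)))  # full precision kept

  # a single fraction collapses mean = min = max
  p1 <- summarize_patient(ms(0.1, 0.1), fracs[1])
  expect_equal(unname(p1$mean), unname(p1$min))
  expect_equal(unname(p1$mean), unname(p1$max))

  # fraction order never matters
  p_perm <- summarize_patient(ms(0.06, 0.11), fracs[c(3, 1, 2)], patient_id = 1)
  expect_equal(as.data.frame(p_perm), row)

  expect_error(summarize_patient(ms(0.1, 0.1), list()),
               class = "cinegate_invalid_argument")
})

test_that("simulation motion is checked against the treatment range inclusively", {
  tbl <- read_motion_table()
  ps <- patient_summaries(tbl)

  r1 <- sim_vs_treatment(ps[[1]])       # sim 0.06 in 0.06-0.11
  expect_true(all(r1$consistent))
  r2 <- sim_vs_treatment(ps[[2]])       # sim 0.15 at the 0.15 boundary
  expect_true(all(r2$consistent))

  bad <- patient_motion_summary("x", sim = c(ap = 0.30, cc = 0.10),
                                mean = c(ap = 0.10, cc = 0.10),
                                min = c(ap = 0.05, cc = 0.05),
                                max = c(ap = 0.15, cc = 0.15))
  rb <- sim_vs_treatment(bad)
  expect_false(rb$consistent[rb$axis == "ap"])
  expect_equal(rb$excess[rb$axis == "ap"], 0.15)
  expect_true(rb$consistent[rb$axis == "cc"])
})

test_that("cohort ranges over the bundled table match the published extrema", {
  tbl <- read_motion_table()
  ps <- patient_summaries(tbl)
  fb <- ps[vapply(ps, function(p) p$gating == "FB", logical(1))]
  dibh <- ps[vapply(ps, function(p) p$gating == "DIBH", logical(1))]

  expect_equal(cohort_range(fb, fields = c("min", "max")),
               c(min = 0.04, max = 0.17))
  expect_equal(cohort_range(fb, fields = "mean", axes = "ap"),
               c(min = 0.07, max = 0.12))
  expect_equal(cohort_range(fb, fields = "mean", axes = "cc"),
               c(min = 0.06, max = 0.12))
  expect_equal(cohort_range(dibh, fields = c("min", "max")),
               c(min = 0.04, max = 0.22))
  expect_equal(cohort_range(ps[1], fields = c("min", "max")),
               c(min = 0.06, max = 0.12))
  expect_error(cohort_range(list()), class = "cinegate_invalid_argument")
})

test_that("the gating rule counts pixels and applies an inclusive 5% threshold", {
  inside <- make_gating_masks(n_gtv = 20, n_outside = 0)
  outside <- make_gating_masks(n_gtv = 20, n_outside = 20)
  ten_pct <- make_gating_masks(n_gtv = 20, n_outside = 2)
  five_pct <- make_gating_masks(n_gtv = 20, n_outside = 1)

  g <- gating_trace(list(inside, outside, ten_pct, five_pct))
  expect_equal(g$fraction_outside, c(0, 1, 0.10, 0.05))
  expect_equal(g$beam_on, c(TRUE, FALSE, FALSE, TRUE))  # beam on at exactly 5%
  expect_equal(attr(g, "duty_cycle"), 0.5)

  # duty cycle is non-decreasing in the threshold
  fracs <- lapply(0:10, function(k) make_gating_masks(20, k))
  duties <- vapply(seq(0, 1, by = 0.1), function(th)
    attr(gating_trace(fracs, threshold = th), "duty_cycle"), numeric(1))
  expect_true(all(diff(duties) >= 0))

  # and non-increasing as the boundary shrinks around a fixed GTV
  shrink <- function(m, extra) make_gating_masks(20, extra)
  d_wide <- attr(gating_trace(lapply(0:3, shrink, m = NULL)), "duty_cycle")
  d_narrow <- attr(gating_trace(lapply(2:5, shrink, m = NULL)), "duty_cycle")
  expect_lte(d_narrow, d_wide)
})

test_that("gating over a rendered cine keeps the beam on while inside", {
  # static lesion well inside its margin-expanded boundary: duty cycle 1
  cine <- make_fb_cine(amplitude_ap = 0, amplitude_cc = 0, duration = 3)
  g <- gate_cine(cine$stack)
  expect_equal(attr(g, "duty_cycle"), 1.0)
  expect_true(all(g$fraction_outside == 0))
})

test_that("the consensus boundary survives occlusion by the moving GTV contour", {
  # the red contour overdraws part of the yellow ring when the lesion
  # approaches the boundary; the static-boundary vote must recover it
  cine <- make_fb_cine(amplitude_ap = 0.15, amplitude_cc = 0.2,
                       duration = 20, seed = 6)
  masks <- lapply(cine$stack$frames, segment_overlay)
  n_occluded <- sum(!vapply(masks, `[[`, logical(1), "boundary_valid"))
  expect_gt(n_occluded, 0)                       # occlusion actually occurs

  g_static <- gating_trace(masks, static_boundary = TRUE)
  expect_equal(attr(g_static, "duty_cycle"), 1.0)
  expect_true(all(g_static$fraction_outside == 0))

  # per-frame semantics exclude exactly the occluded frames
  g_frame <- gating_trace(masks, static_boundary = FALSE)
  expect_length(attr(g_frame, "excluded_frames"), n_occluded)
})
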