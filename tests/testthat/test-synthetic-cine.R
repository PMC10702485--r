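test_that("degenerate and sinusoidal traces follow their closed forms", {
  # zero amplitude, drift and noise: constant at the rest position
  tr <- generate_trace(motion_model("FB", amplitude_ap = 0, amplitude_cc = 0),
                       duration = 10, frame_rate = 4,
                       rest_center = c(3.5, 7.0))
  expect_equal(nrow(tr), 40L)
  expect_true(all(tr$ap_cm == 3.5) && all(tr$cc_cm == 7.0))

  # sinusoid over whole periods: population SD is exactly A/sqrt(2);
  # the sample SD differs only by the sqrt(n/(n-1)) factor
  tr <- generate_trace(motion_model("FB", amplitude_ap = 0,
                                    amplitude_cc = 0.5, period = 4),
                       duration = 60, frame_rate = 4)
  n <- nrow(tr)
  pop_sd <- sqrt(sum((tr$cc_cm - mean(tr$cc_cm))^2) / n)
  expect_equal(pop_sd, 0.5 / sqrt(2), tolerance = 1e-9)
  expect_lt(abs(sd(tr$cc_cm) - 0.3536), 1e-3)
})

test_that("DIBH traces carry the configured breath-hold structure", {
  m <- motion_model("DIBH", plateau_duration = 15, n_holds = 6,
                    inter_hold_fb_duration = 5, intra_hold_jitter_sd = 0)
  tr <- generate_trace(m, duration = 130, frame_rate = 4, seed = 1)
  runs <- rle(tr$label)
  dip_runs <- runs$lengths[runs$values == "DIP"]
  expect_length(dip_runs, 6L)
  expect_true(all(dip_runs == 15 * 4))          # each hold exactly 15 s
  expect_equal(sum(tr$label == "DIP"), 6L * 60L)
  expect_length(tr$label, nrow(tr))             # labels cover all frames
  # too short a cine for the requested holds is rejected
  expect_error(generate_trace(m, duration = 30, frame_rate = 4),
               class = "cinegate_invalid_argument")
})

test_that("the generator is deterministic under a fixed seed", {
  m <- motion_model("FB", amplitude_cc = 0.3, noise_sd = 0.05)
  t1 <- generate_trace(m, 15, 4, seed = 11)
  t2 <- generate_trace(m, 15, 4, seed = 11)
  expect_identical(t1, t2)
  t3 <- generate_trace(m, 15, 4, seed = 12)
  expect_false(identical(t1$cc_cm, t3$cc_cm))

  les <- lesion_spec()
  cfg <- render_config(background = "textured",
                       compression_noise = "mild", seed = 5)
  tr <- generate_trace(m, 3, 4, seed = 11, rest_center = les$rest_center)
  s1 <- render_frames(tr, les, cfg = cfg)
  s2 <- render_frames(tr, les, cfg = cfg)
  expect_identical(s1$frames, s2$frames)
})

test_that("rendered frames contain exact overlays over pure grayscale", {
  cine <- make_fb_cine(amplitude_ap = 0, amplitude_cc = 0, duration = 10)
  expect_length(cine$stack$frames, 40L)         # 10 s at 4 Hz

  fr <- cine$stack$frames[[1]]
  red <- fr[, , 1] == 255 & fr[, , 2] == 0 & fr[, , 3] == 0
  yellow <- fr[, , 1] == 255 & fr[, , 2] == 255 & fr[, , 3] == 0
  other <- !(red | yellow)
  expect_gt(sum(red), 0)
  expect_gt(sum(yellow), 0)
  # overlay purity: every non-overlay pixel is grayscale
  expect_true(all((fr[, , 1] == fr[, , 2] & fr[, , 2] == fr[, , 3])[other]))
})

test_that("noise-free rendering places the contour at the true centroid", {
  cine <- make_fb_cine(amplitude_ap = 0.2, amplitude_cc = 0.3, duration = 5)
  for (i in c(1, 7, 20)) {
    m <- segment_overlay(cine$stack$frames[[i]])
    got <- mask_centroid(m$gtv_region_mask, cine$stack$pixel_spacing)
    want <- oracle_centroid(m$gtv_region_mask, cine$stack$pixel_spacing)
    expect_equal(got, want, tolerance = 1e-12)  # matches brute-force mean
    expect_lt(abs(got[["ap"]] - cine$truth$ap_cm[i]), 0.5 * 0.35)
    expect_lt(abs(got[["cc"]] - cine$truth$cc_cm[i]), 0.5 * 0.35)
  }
})

test_that("a lesion leaving the field of view is rejected with the frame index", {
  les <- lesion_spec(rest_center = c(3.0, 3.0))   # close to the image edge
  tr <- generate_trace(motion_model("FB", amplitude_cc = 2.5, period = 8),
                       10, 4, rest_center = les$rest_center)
  err <- expect_error(render_frames(tr, les), class = "cinegate_out_of_bounds")
  expect_match(conditionMessage(err), "frame \\d+")
})

test_that("png stacks round-trip losslessly with zero-padded names", {
  cine <- make_fb_cine(duration = 3, noise = "off")
  dir <- withr::local_tempdir()
  files <- write_cine(cine$stack, dir, format = "png_stack")
  expect_length(files, 12L)
  expect_match(basename(files[1]), "^frame_0001\\.png$")
  back <- read_cine(dir, "png_stack",
                    pixel_spacing = cine$stack$pixel_spacing, frame_rate = 4)
  expect_identical(back$frames, cine$stack$frames)

  expect_error(write_cine(cine$stack, file.path(dir, "frame_0001.png")),
               class = "cinegate_io_error")  # path exists as a file
  expect_error(write_cine(cine$stack, dir, format = "mp4"),
               class = "cinegate_io_error")
})

test_that("mild compression noise leaves the segmented GTV nearly intact", {
  clean <- make_fb_cine(duration = 3, seed = 9, noise = "off")
  noisy <- make_fb_cine(duration = 3, seed = 9, noise = "mild")
  for (i in c(1, 6, 12)) {
    a <- segment_overlay(clean$stack$frames[[i]])$gtv_region_mask
    b <- segment_overlay(noisy$stack$frames[[i]])$gtv_region_mask
    iou <- sum(a & b) / sum(a | b)
    expect_gte(iou, 0.9)
  }
})

test_that("simulation configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sim.yaml")
  yaml::write_yaml(list(model = list(kind = "DIBH", n_holds = 3,
                                     plateau_duration = 10),
                        lesion = list(semi_axes = c(0.8, 1.2),
                                      rest_center = c(10, 12)),
                        render = list(compression_noise = "mild")),
                   path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg$model, "motion_model")
  expect_equal(cfg$model$n_holds, 3L)
  expect_equal(cfg$lesion$semi_axes, c(ap = 0.8, cc = 1.2))
  expect_equal(cfg$render$compression_noise, "mild")
  expect_s3_class(cfg$boundary, "boundary_spec")  # derived from the lesion
})
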