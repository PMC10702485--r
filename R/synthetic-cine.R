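#' Respiratory motion model for synthetic cine generation
#'
#' Describes how the GTV centroid moves in the sagittal plane. Two kinds are
#' supported, mirroring the two gating strategies:
#'
#' * `"FB"` (free breathing): a sinusoid per axis plus an optional linear
#'   baseline drift and per-frame Gaussian jitter.
#' * `"DIBH"` (deep-inspiration breath-hold): free-breathing segments
#'   alternating with quasi-static plateaus displaced to `plateau_level`,
#'   with small Gaussian jitter inside each hold. Transitions between the
#'   two regimes are instantaneous; the analysis never depends on the shape
#'   of the transition itself.
#'
#' Default magnitudes emulate apical lung lesions on a 0.35 T MR-Linac:
#' free-breathing centroid SDs of roughly 0.04–0.17 cm (so amplitudes of
#' 0.06–0.24 cm, since SD = amplitude/sqrt(2) for a sinusoid), larger
#' free-breathing excursions of 0.2–1.4 cm amplitude for patients who end
#' up treated in breath-hold, an inspiration displacement of ~1 cm CC, and
#' intra-hold jitter of a few hundredths of a cm.
#'
#' @param kind `"FB"` or `"DIBH"`.
#' @param amplitude_ap,amplitude_cc sinusoid amplitude per axis (cm) used
#'   for free breathing (and for the free-breathing segments of a DIBH
#'   cine).
#' @param period breathing period (s).
#' @param phase phase offset (rad).
#' @param drift_rate length-2 numeric `(ap, cc)`: linear baseline drift
#'   (cm/s) applied during free-breathing segments.
#' @param noise_sd per-frame Gaussian jitter SD (cm) during free breathing.
#' @param plateau_level length-2 numeric `(ap, cc)`: displacement of the
#'   lesion at deep inspiration relative to the rest position (cm).
#' @param plateau_duration duration of each breath-hold (s).
#' @param n_holds number of breath-holds (>= 1).
#' @param inter_hold_fb_duration free-breathing time between holds (s).
#' @param intra_hold_jitter_sd per-frame Gaussian jitter SD inside a hold
#'   (cm).
#' @return an object of class `motion_model`.
#' @seealso [generate_trace()]
#' @export
motion_model <- function(kind = c("FB", "DIBH"),
                         amplitude_ap = 0.10, amplitude_cc = 0.15,
                         period = 4, phase = 0,
                         drift_rate = c(ap = 0, cc = 0),
                         noise_sd = 0,
                         plateau_level = c(ap = 0.3, cc = 1.0),
                         plateau_duration = 15, n_holds = 6,
                         inter_hold_fb_duration = 5,
                         intra_hold_jitter_sd = 0.03) {
  kind <- match.arg(kind)
  assert_scalar_num(amplitude_ap, "amplitude_ap", lower = 0)
  assert_scalar_num(amplitude_cc, "amplitude_cc", lower = 0)
  assert_scalar_num(period, "period", lower = 0, strict_lower = TRUE)
  assert_scalar_num(phase, "phase")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(drift_rate) == 2L, is.numeric(drift_rate))
  if (kind == "DIBH") {
    stopifnot(length(plateau_level) == 2L, is.numeric(plateau_level))
    assert_scalar_num(plateau_duration, "plateau_duration", lower = 0,
                      strict_lower = TRUE)
    assert_scalar_num(n_holds, "n_holds", lower = 1)
    assert_scalar_num(inter_hold_fb_duration, "inter_hold_fb_duration",
                      lower = 0)
    assert_scalar_num(intra_hold_jitter_sd, "intra_hold_jitter_sd", lower = 0)
  }
  structure(list(kind = kind,
                 amplitude_ap = amplitude_ap, amplitude_cc = amplitude_cc,
                 period = period, phase = phase,
                 drift_rate = stats::setNames(as.numeric(drift_rate),
                                              c("ap", "cc")),
                 noise_sd = noise_sd,
                 plateau_level = stats::setNames(as.numeric(plateau_level),
                                                 c("ap", "cc")),
                 plateau_duration = plateau_duration,
                 n_holds = as.integer(n_holds),
                 inter_hold_fb_duration = inter_hold_fb_duration,
                 intra_hold_jitter_sd = intra_hold_jitter_sd),
            class = "motion_model")
}

#' Lesion geometry for synthetic rendering
#'
#' The tracked structure (GTV cross-section in the sagittal plane) as a
#' rigid shape translated by the motion model. The default 1.0 x 1.5 cm
#' semi-axis ellipse corresponds to a GTV of a few cc, in the middle of the
#' range seen for apical lung lesions.
#'
#' @param shape `"ellipse"` or `"polygon"`.
#' @param semi_axes length-2 `(ap, cc)` semi-axes in cm (ellipse).
#' @param vertices two-column matrix of `(ap, cc)` vertex offsets in cm
#'   relative to the shape centroid (polygon).
#' @param rest_center length-2 `(ap, cc)` rest position of the lesion
#'   centroid in cm from the image origin (top-posterior corner). The
#'   default sits deliberately off the pixel grid: a centroid aligned
#'   exactly with pixel edges is a degenerate symmetric configuration
#'   (boundary rows rasterise in unison) that does not occur in practice.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("ellipse", "polygon"),
                        semi_axes = c(ap = 1.0, cc = 1.5),
                        vertices = NULL,
                        rest_center = c(ap = 16.93, cc = 17.02)) {
  shape <- match.arg(shape)
  stopifnot(length(rest_center) == 2L, is.numeric(rest_center))
  if (shape == "ellipse") {
    stopifnot(length(semi_axes) == 2L, is.numeric(semi_axes))
    if (any(semi_axes <= 0))
      stopf("lesion semi-axes must be positive",
            class = "cinegate_invalid_argument")
    semi_axes <- stats::setNames(as.numeric(semi_axes), c("ap", "cc"))
    vertices <- NULL
  } else {
    if (is.null(vertices) || !is.matrix(vertices) || ncol(vertices) != 2L ||
        nrow(vertices) < 3L)
      stopf("polygon lesions need a >= 3 row, 2 column vertex matrix",
            class = "cinegate_invalid_argument")
    # re-centre so the polygon centroid sits at the origin
    vertices <- sweep(vertices, 2L, colMeans(vertices))
    semi_axes <- NULL
  }
  structure(list(shape = shape, semi_axes = semi_axes, vertices = vertices,
                 rest_center = stats::setNames(as.numeric(rest_center),
                                               c("ap", "cc"))),
            class = "lesion_spec")
}

#' Gating boundary geometry
#'
#' A static contour (in clinical use the PTV or an isodose surface) drawn
#' in yellow on every frame. [boundary_for()] builds the usual case: the
#' lesion expanded by an isotropic margin, centred at its rest position.
#'
#' @param shape `"ellipse"` or `"rect"`.
#' @param center length-2 `(ap, cc)` centre in cm.
#' @param semi_axes length-2 `(ap, cc)` semi-axes (ellipse) or half-sizes
#'   (rect) in cm.
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(shape = c("ellipse", "rect"),
                          center, semi_axes) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(semi_axes <= 0))
    stopf("boundary semi-axes must be positive",
          class = "cinegate_invalid_argument")
  structure(list(shape = shape,
                 center = stats::setNames(as.numeric(center), c("ap", "cc")),
                 semi_axes = stats::setNames(as.numeric(semi_axes),
                                             c("ap", "cc"))),
            class = "boundary_spec")
}

#' @param lesion a [lesion_spec()].
#' @param margin isotropic expansion in cm (default 0.5, the standard
#'   free-breathing GTV-to-PTV margin).
#' @rdname boundary_spec
#' @export
boundary_for <- function(lesion, margin = 0.5) {
  stopifnot(inherits(lesion, "lesion_spec"))
  half <- if (lesion$shape == "ellipse") lesion$semi_axes
          else apply(abs(lesion$vertices), 2L, max)
  boundary_spec("ellipse", center = lesion$rest_center,
                semi_axes = half + margin)
}

#' Rendering configuration for synthetic cine frames
#'
#' Controls the rasterisation of overlay frames. Defaults follow the
#' clinical acquisition: 4 frames/s sagittal cine with 0.35 cm in-plane
#' pixels (the 0.5 cm of the nominal "0.35 x 0.5 cm^2" resolution is the
#' slice thickness, kept as metadata; fully anisotropic in-plane spacing is
#' supported through `pixel_spacing` for the alternative reading), red GTV
#' contour and yellow gating boundary over grayscale anatomy.
#'
#' With `compression_noise = "off"` every non-overlay pixel is exactly
#' grayscale (R = G = B) and overlay pixels are exactly the configured
#' colors. `"mild"` perturbs every channel by an integer uniform in
#' +/- 20 (8-bit), emulating the chroma errors of a lossy mp4 export.
#'
#' @param image_size integer `(rows, cols)`.
#' @param pixel_spacing `(row, col)` spacing in cm/pixel.
#' @param slice_thickness slice thickness in cm (metadata only).
#' @param frame_rate frames per second.
#' @param gtv_color,boundary_color RGB triples in 0–255; must differ from
#'   each other and must not be grayscale.
#' @param contour_thickness contour thickness in pixels.
#' @param background `"flat"` or `"textured"` grayscale anatomy.
#' @param compression_noise `"off"` or `"mild"`.
#' @param seed integer seed for texture and compression noise.
#' @return an object of class `render_config`.
#' @export
render_config <- function(image_size = c(96L, 96L),
                          pixel_spacing = c(0.35, 0.35),
                          slice_thickness = 0.5,
                          frame_rate = 4,
                          gtv_color = c(255, 0, 0),
                          boundary_color = c(255, 255, 0),
                          contour_thickness = 1L,
                          background = c("flat", "textured"),
                          compression_noise = c("off", "mild"),
                          seed = NULL) {
  background <- match.arg(background)
  compression_noise <- match.arg(compression_noise)
  stopifnot(length(image_size) == 2L, length(pixel_spacing) == 2L,
            length(gtv_color) == 3L, length(boundary_color) == 3L)
  if (any(pixel_spacing <= 0) || frame_rate <= 0)
    stopf("pixel spacing and frame rate must be positive",
          class = "cinegate_invalid_argument")
  is_gray <- function(col) col[1] == col[2] && col[2] == col[3]
  if (is_gray(gtv_color) || is_gray(boundary_color) ||
      all(gtv_color == boundary_color))
    stopf("overlay colors must be non-grayscale and distinct",
          class = "cinegate_invalid_argument")
  assert_scalar_num(contour_thickness, "contour_thickness", lower = 1)
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = slice_thickness,
                 frame_rate = frame_rate,
                 gtv_color = as.integer(gtv_color),
                 boundary_color = as.integer(boundary_color),
                 contour_thickness = as.integer(contour_thickness),
                 background = background,
                 compression_noise = compression_noise,
                 seed = seed),
            class = "render_config")
}

#' Generate a ground-truth centroid trace from a motion model
#'
#' Samples the motion model at the cine frame rate and returns the true
#' per-frame centroid position together with a breathing-phase label for
#' every frame (`"DIP"` for deep-inspiration plateaus, `"FBP"` otherwise).
#' For DIBH models the cine is laid out as alternating free-breathing and
#' plateau blocks, starting and ending in free breathing; `duration` must
#' be long enough to contain all `n_holds` holds, and any surplus extends
#' the final free-breathing block.
#'
#' @param model a [motion_model()].
#' @param duration cine length in s (>= one frame period).
#' @param frame_rate sampling rate in Hz (default 4, the clinical cine
#'   rate).
#' @param seed integer; the same seed reproduces the trace bit-for-bit.
#' @param rest_center length-2 `(ap, cc)` position about which the motion
#'   is expressed (cm); usually the lesion's rest position.
#' @return a `ground_truth` data frame with columns `frame`, `t_s`,
#'   `ap_cm`, `cc_cm`, `label`, and the model and frame rate as attributes.
#' @examples
#' tr <- generate_trace(motion_model("FB", amplitude_cc = 0.5, period = 4),
#'                      duration = 60, seed = 1)
#' sd(tr$cc_cm)  # ~ 0.5 / sqrt(2)
#' @export
generate_trace <- function(model, duration, frame_rate = 4, seed = NULL,
                           rest_center = c(ap = 0, cc = 0)) {
  stopifnot(inherits(model, "motion_model"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(frame_rate) ||
      frame_rate <= 0)
    stopf("duration and frame_rate must be positive",
          class = "cinegate_invalid_argument")
  if (duration < 1 / frame_rate)
    stopf("duration shorter than one frame period",
          class = "cinegate_invalid_argument")
  n <- floor(duration * frame_rate)
  t <- (seq_len(n) - 1L) / frame_rate

  with_seed(seed, {
    sinus <- function(amp) amp * sin(2 * pi * t / model$period + model$phase)
    if (model$kind == "FB") {
      ap <- sinus(model$amplitude_ap) + model$drift_rate[["ap"]] * t
      cc <- sinus(model$amplitude_cc) + model$drift_rate[["cc"]] * t
      if (model$noise_sd > 0) {
        ap <- ap + rnorm(n, sd = model$noise_sd)
        cc <- cc + rnorm(n, sd = model$noise_sd)
      }
      label <- rep("FBP", n)
    } else {
      fb_n <- round(model$inter_hold_fb_duration * frame_rate)
      dip_n <- round(model$plateau_duration * frame_rate)
      needed <- (model$n_holds + 1L) * fb_n + model$n_holds * dip_n
      if (n < needed)
        stopf(paste0("duration %.1f s is too short for %d holds of %.1f s ",
                     "separated by %.1f s of free breathing (needs %.1f s)"),
              duration, model$n_holds, model$plateau_duration,
              model$inter_hold_fb_duration, needed / frame_rate,
              class = "cinegate_invalid_argument")
      is_dip <- logical(n)
      pos <- fb_n
      for (h in seq_len(model$n_holds)) {
        is_dip[(pos + 1L):(pos + dip_n)] <- TRUE
        pos <- pos + dip_n + fb_n
      }
      ap <- sinus(model$amplitude_ap) + model$drift_rate[["ap"]] * t
      cc <- sinus(model$amplitude_cc) + model$drift_rate[["cc"]] * t
      if (model$noise_sd > 0) {
        ap <- ap + rnorm(n, sd = model$noise_sd)
        cc <- cc + rnorm(n, sd = model$noise_sd)
      }
      ndip <- sum(is_dip)
      jit_ap <- if (model$intra_hold_jitter_sd > 0)
        rnorm(ndip, sd = model$intra_hold_jitter_sd) else numeric(ndip)
      jit_cc <- if (model$intra_hold_jitter_sd > 0)
        rnorm(ndip, sd = model$intra_hold_jitter_sd) else numeric(ndip)
      ap[is_dip] <- model$plateau_level[["ap"]] + jit_ap
      cc[is_dip] <- model$plateau_level[["cc"]] + jit_cc
      label <- ifelse(is_dip, "DIP", "FBP")
    }
    out <- data.frame(frame = seq_len(n),
                      t_s = t,
                      ap_cm = as.numeric(rest_center[[1]]) + ap,
                      cc_cm = as.numeric(rest_center[[2]]) + cc,
                      label = label)
    structure(out, class = c("ground_truth", "data.frame"),
              model = model, frame_rate = frame_rate,
              rest_center = stats::setNames(as.numeric(rest_center),
                                            c("ap", "cc")))
  })
}

## pixel-centre coordinate grids for a render configuration
pixel_centers <- function(cfg) {
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  list(ap = (seq_len(nc) - 0.5) * cfg$pixel_spacing[2],
       cc = (seq_len(nr) - 0.5) * cfg$pixel_spacing[1])
}

#' Rasterise the lesion region at a given centroid position
#'
#' Returns the filled binary mask (rows x cols) of the lesion translated so
#' its centroid lies at `center`, using the pixel-centre convention. This
#' is the geometric ground truth the overlay renderer draws, exposed so
#' tests and QC can compare segmentation output against it.
#'
#' @param lesion a [lesion_spec()].
#' @param center length-2 `(ap, cc)` centroid position in cm.
#' @param cfg a [render_config()].
#' @return a logical matrix of the configured image size.
#' @export
rasterize_lesion <- function(lesion, center, cfg) {
  px <- pixel_centers(cfg)
  if (lesion$shape == "ellipse") {
    a <- lesion$semi_axes[[1]]; b <- lesion$semi_axes[[2]]
    dap2 <- ((px$ap - center[[1]]) / a)^2
    dcc2 <- ((px$cc - center[[2]]) / b)^2
    outer(dcc2, dap2, `+`) <= 1
  } else {
    pts <- expand.grid(cc = px$cc, ap = px$ap)
    verts <- sweep(lesion$vertices, 2L, c(center[[1]], center[[2]]), `+`)
    inside <- mgcv::in.out(verts[, c(1, 2), drop = FALSE],
                           as.matrix(pts[, c("ap", "cc")]))
    matrix(inside, nrow = length(px$cc), ncol = length(px$ap))
  }
}

rasterize_boundary <- function(boundary, cfg) {
  px <- pixel_centers(cfg)
  dap <- px$ap - boundary$center[[1]]
  dcc <- px$cc - boundary$center[[2]]
  if (boundary$shape == "ellipse") {
    outer((dcc / boundary$semi_axes[[2]])^2,
          (dap / boundary$semi_axes[[1]])^2, `+`) <= 1
  } else {
    outer(abs(dcc) <= boundary$semi_axes[[2]],
          abs(dap) <= boundary$semi_axes[[1]], `&`)
  }
}

contour_of <- function(region, thickness) {
  region & !erode3(region, iter = thickness)
}

lesion_extent <- function(lesion) {
  if (lesion$shape == "ellipse") lesion$semi_axes
  else apply(abs(lesion$vertices), 2L, max)
}

#' Render synthetic cine frames with tracking overlays
#'
#' Draws, for every sample of a ground-truth trace, the grayscale anatomy
#' background, the static yellow gating boundary contour, and the red GTV
#' contour translated to the true centroid — emulating the overlay frames
#' the treatment delivery system exports. Overlays are drawn last (GTV on
#' top), so in noise-free mode every overlay pixel is exactly its
#' configured color and every other pixel is exactly grayscale.
#'
#' @param truth a `ground_truth` trace from [generate_trace()].
#' @param lesion a [lesion_spec()].
#' @param boundary a [boundary_spec()] (or `NULL` for no boundary overlay).
#' @param cfg a [render_config()].
#' @return a `frame_stack`: list with `frames` (list of rows x cols x 3
#'   integer arrays, 0–255), `pixel_spacing`, `frame_rate`, `source`.
#' @export
render_frames <- function(truth, lesion, boundary = boundary_for(lesion),
                          cfg = render_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(lesion, "lesion_spec"))
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  fov <- c(ap = nc * cfg$pixel_spacing[2], cc = nr * cfg$pixel_spacing[1])
  ext <- lesion_extent(lesion) + cfg$contour_thickness * max(cfg$pixel_spacing)
  bad <- which(truth$ap_cm - ext[[1]] < 0 | truth$ap_cm + ext[[1]] > fov[["ap"]] |
               truth$cc_cm - ext[[2]] < 0 | truth$cc_cm + ext[[2]] > fov[["cc"]])
  if (length(bad))
    stopf("lesion leaves the field of view at frame %d", bad[1],
          class = "cinegate_out_of_bounds")

  with_seed(cfg$seed, {
    bg <- if (cfg$background == "flat") {
      matrix(90L, nr, nc)
    } else {
      # smooth pseudo-anatomical texture: low-frequency sinusoids + blurred noise
      rows <- seq_len(nr); cols <- seq_len(nc)
      field <- 100 + 30 * outer(sin(rows / 9), cos(cols / 13)) +
        20 * outer(cos(rows / 23 + 1), sin(cols / 17))
      noise <- matrix(rnorm(nr * nc, sd = 12), nr, nc)
      noise <- (noise + shift_mat(noise, 1, 0) + shift_mat(noise, -1, 0) +
                  shift_mat(noise, 0, 1) + shift_mat(noise, 0, -1)) / 5
      matrix(as.integer(pmin(170, pmax(30, round(field + noise)))), nr, nc)
    }
    bmask <- if (is.null(boundary)) matrix(FALSE, nr, nc)
             else contour_of(rasterize_boundary(boundary, cfg),
                             cfg$contour_thickness)
    n <- nrow(truth)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      region <- rasterize_lesion(lesion,
                                 c(truth$ap_cm[i], truth$cc_cm[i]), cfg)
      ring <- contour_of(region, cfg$contour_thickness)
      arr <- array(0L, dim = c(nr, nc, 3L))
      for (ch in 1:3) {
        plane <- bg
        plane[bmask] <- cfg$boundary_color[ch]
        plane[ring] <- cfg$gtv_color[ch]
        arr[, , ch] <- plane
      }
      if (cfg$compression_noise == "mild") {
        pert <- array(sample.int(41L, nr * nc * 3L, replace = TRUE) - 21L,
                      dim = dim(arr))
        arr <- array(pmin(255L, pmax(0L, arr + pert)), dim = dim(arr))
      }
      frames[[i]] <- arr
    }
    frame_stack(frames, pixel_spacing = cfg$pixel_spacing,
                frame_rate = cfg$frame_rate, source = "synthetic")
  })
}

#' Write a cine to disk
#'
#' `"png_stack"` writes one losslessly-compressed PNG per frame into
#' `path` (created if needed), named `frame_0001.png`, `frame_0002.png`,
#' ... so that lexicographic order is temporal order. Reading the stack
#' back with [read_cine()] reproduces the pixel arrays exactly. The mp4
#' container used by the delivery system requires an H.264 encoder, which
#' this package does not bundle; requesting `"mp4"` raises an error, and
#' lossy-compression effects can instead be emulated at render time with
#' `compression_noise = "mild"`.
#'
#' @param stack a `frame_stack`.
#' @param path output directory (png_stack) or file (mp4).
#' @param format `"png_stack"` or `"mp4"`.
#' @return invisibly, the written file paths.
#' @export
write_cine <- function(stack, path, format = c("png_stack", "mp4")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) == 0L)
    stopf("empty frame stack", class = "cinegate_invalid_argument")
  if (format == "mp4")
    stopf(paste("mp4 output requires an external H.264 encoder;",
                "use format = 'png_stack', or emulate lossy compression",
                "with render_config(compression_noise = 'mild')"),
          class = "cinegate_io_error")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE))
    stopf("cannot create directory '%s'", path, class = "cinegate_io_error")
  n <- length(stack$frames)
  width <- max(4L, nchar(n))
  files <- file.path(path, sprintf(paste0("frame_%0", width, "d.png"),
                                   seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(stack$frames[[i]] / 255, target = files[i])
  invisible(files)
}

#' Read model, lesion and render settings from a YAML file
#'
#' The file may contain top-level `model`, `lesion`, `boundary` and
#' `render` sections whose keys match the arguments of [motion_model()],
#' [lesion_spec()], [boundary_spec()] and [render_config()]; missing
#' sections fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a list with elements `model`, `lesion`, `boundary`, `render`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stopf("config file '%s' not found", path, class = "cinegate_io_error")
  raw <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  lesion <- build(lesion_spec, raw$lesion)
  boundary <- if (is.null(raw$boundary)) boundary_for(lesion)
              else build(boundary_spec, raw$boundary)
  list(model = build(motion_model, raw$model),
       lesion = lesion, boundary = boundary,
       render = build(render_config, raw$render))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
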