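#' Frame stack container
#'
#' An ordered set of RGB cine frames plus the geometry needed to express
#' positions in cm: in-plane pixel spacing and the frame rate. Frames are
#' stored as `rows x cols x 3` integer arrays with 8-bit values (0–255);
#' rows run cranio-caudal, columns antero-posterior.
#'
#' @param frames list of `rows x cols x 3` numeric/integer arrays, all the
#'   same shape.
#' @param pixel_spacing `(row, col)` spacing in cm/pixel.
#' @param frame_rate frames per second.
#' @param source optional provenance string (path or `"synthetic"`).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_spacing = c(0.35, 0.35),
                        frame_rate = 4, source = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stopf("`frames` must be a non-empty list of RGB arrays",
          class = "cinegate_invalid_argument")
  dims <- lapply(frames, dim)
  ok <- vapply(dims, function(d) length(d) == 3L && d[3] == 3L, logical(1))
  if (!all(ok))
    stopf("all frames must be rows x cols x 3 arrays",
          class = "cinegate_format_error")
  ref <- dims[[1]]
  if (!all(vapply(dims, identical, logical(1), y = ref)))
    stopf("frames have inconsistent sizes (first mismatch at frame %d)",
          which(!vapply(dims, identical, logical(1), y = ref))[1],
          class = "cinegate_format_error")
  if (any(pixel_spacing <= 0) || frame_rate <= 0)
    stopf("pixel spacing and frame rate must be positive",
          class = "cinegate_invalid_argument")
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame_rate = frame_rate,
                 source = source),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(paste0("<frame_stack> %d frames, %d x %d px, ",
                     "%.3g x %.3g cm/px, %.3g fps\n"),
              length(x$frames), d[1], d[2],
              x$pixel_spacing[1], x$pixel_spacing[2], x$frame_rate))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Read an exported cine into a frame stack
#'
#' Reads a PNG frame stack (a directory of per-frame PNGs in lexicographic
#' = temporal order, as written by [write_cine()] or by an external frame
#' exporter). The mp4 container itself is not decoded — frames must first
#' be extracted to images, which is also how the clinical workflow consumes
#' the exported video.
#'
#' @param path directory containing the PNG frames.
#' @param format only `"png_stack"` is supported.
#' @param pixel_spacing `(row, col)` spacing in cm/pixel.
#' @param frame_rate frames per second.
#' @return a `frame_stack`.
#' @export
read_cine <- function(path, format = c("png_stack", "mp4"),
                      pixel_spacing = c(0.35, 0.35), frame_rate = 4) {
  format <- match.arg(format)
  if (format == "mp4")
    stopf(paste("mp4 decoding requires an external decoder; extract the",
                "frames to PNG first and read them as a png_stack"),
          class = "cinegate_io_error")
  if (!dir.exists(path))
    stopf("'%s' is not a readable directory", path,
          class = "cinegate_io_error")
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stopf("no PNG frames found in '%s'", path, class = "cinegate_io_error")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L)            # grayscale -> replicate channels
      img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    array(as.integer(round(img * 255)), dim = dim(img))
  })
  frame_stack(frames, pixel_spacing = pixel_spacing,
              frame_rate = frame_rate, source = path)
}
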