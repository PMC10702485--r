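## internal helpers shared across modules

stopf <- function(fmt, ..., class = "cinegate_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cinegate_error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name,
          class = "cinegate_invalid_argument")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stopf("`%s` = %g is outside its allowed range", name, x,
          class = "cinegate_invalid_argument")
  invisible(x)
}

#' Round half away from zero
#'
#' Report-style rounding: halves round away from zero (so -2.365 at two
#' decimals becomes -2.37), matching how clinical tables are printed, unlike
#' [round()]'s round-half-even. Used for all human-readable output; internal
#' computations keep full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_scalar_num(seed, "seed")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## binary morphology on logical matrices via shifts (3x3 box kernel applied
## `iter` times); orientation-free, so no dependence on image storage order
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rdst <- rs + dr; cdst <- cs + dc
  keep_r <- rdst >= 1L & rdst <= nr
  keep_c <- cdst >= 1L & cdst <= nc
  out[rdst[keep_r], cdst[keep_c]] <- m[rs[keep_r], cs[keep_c]]
  out
}

dilate3 <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) acc <- acc | shift_mat(m, dr, dc)
    m <- acc
  }
  m
}

erode3 <- function(m, iter = 1L) {
  for (i in seq_len(iter)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) acc <- acc & shift_mat(m, dr, dc, fill = TRUE)
    m <- acc
  }
  m
}

## contiguous runs of TRUE in a logical vector -> matrix of (start, end)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
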