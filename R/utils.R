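deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(190, -180, 360))
wrap_angle <- function(x) {
  w <- x %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a, what = "vector") {
  n <- vnorm(a)
  if (!is.finite(n) || n < 1e-10) {
    abort(paste0("degenerate geometry: zero-length ", what))
  }
  a / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

`%||%` <- rlang::`%||%`
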