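deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10)
    stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# coerce x to an n x 3 matrix (rows = points)
as_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) == 3)
    matrix(x, ncol = 3)
  }
}
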