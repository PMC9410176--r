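# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state. With `seed = NULL` the expression runs in the ambient stream.
#'
#' @param seed integer seed or NULL
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotate a 3-vector about an axis (Rodrigues' formula)
#' @keywords internal
rotate_about <- function(v, axis, angle_deg) {
  a <- angle_deg * pi / 180
  k <- unit_vector(axis)
  v * cos(a) + cross3(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Angle between two vectors, degrees in [0, 180]
#' @keywords internal
vector_angle_deg <- function(a, b) {
  ct <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(clamp(ct, -1, 1)) * 180 / pi
}

# Polynomial rolling hash over the serialized object; used to fingerprint
# run configurations in manifests only (not cryptographic).
config_hash <- function(x) {
  bytes <- utils::capture.output(utils::str(x))
  bytes <- utf8ToInt(paste(bytes, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
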