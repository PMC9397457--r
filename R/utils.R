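#' @keywords internal
"_PACKAGE"

# angle unit helpers: degrees at every public interface, radians internally
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# row-wise cross product for n x 3 matrices (Monte-Carlo vectorization)
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

stopifnot_unit <- function(v, what, tol = 1e-9) {
  if (abs(vnorm(v) - 1) > tol)
    stop(sprintf("%s must be a unit vector (|norm - 1| = %.3g)", what,
                 abs(vnorm(v) - 1)), call. = FALSE)
  invisible(v)
}

# Evaluate an expression with a temporary RNG state; the caller's stream is
# untouched, so seeded routines have no global side effects.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x) && x >= 1
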