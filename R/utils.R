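#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that generators are deterministic given a seed and never
#' disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Population standard deviation
#' @param x numeric vector.
#' @return sqrt(mean((x - mean(x))^2)); 0 for length-1 input.
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) stop("pop_sd: empty input")
  sqrt(sum((x - mean(x))^2) / n)
}

# stopifnot-style assertion with a formatted message
assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# squared euclidean distances from an n x 3 matrix to a single point
dist_to_point <- function(xyz, p) {
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
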