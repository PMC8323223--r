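# Internal helpers shared across modules.

# Run an expression with a temporary RNG state seeded from `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round doubles through IEEE 754 single precision (what the binary formats
# store), staying in double storage.
as_float32 <- function(x) {
  dims <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 what = "numeric", n = length(x), size = 4L)
  dim(out) <- dims
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v * v))

normalize3 <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_norms <- function(m) sqrt(rowSums(m * m))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
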