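# Internal helpers shared across modules.

# Validate that `x` is numeric, finite where not NA-allowed, and satisfies a
# predicate; errors name the offending field so upstream readers can report
# the exact column.
check_numeric <- function(x, field, finite = TRUE, allow_na = FALSE) {
  if (!is.numeric(x)) {
    stop(sprintf("field '%s' must be numeric", field), call. = FALSE)
  }
  bad <- if (finite) !is.finite(x) else is.na(x)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    stop(sprintf("field '%s' contains non-finite values", field), call. = FALSE)
  }
  invisible(x)
}

check_that <- function(ok, field, msg) {
  if (!all(ok)) {
    stop(sprintf("field '%s' %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

check_columns <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Round to the nearest multiple of `step`, ties away from zero
# (round() would go to even).
round_step <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

# Dirichlet draws via independent gammas; rows are draws.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Inverse of trigamma by Newton iteration on the log scale
# (monotone decreasing, so the iteration is globally convergent).
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & !is.na(x) & x <= 0] <- Inf
  y <- 0.5 + 1 / x[ok]   # starting value, exact as x -> 0 or Inf
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  out[ok] <- y
  out
}

# md5 of a canonical text rendering of an R object (used for run manifests).
object_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}
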