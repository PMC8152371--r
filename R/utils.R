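#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit, so that package functions
#' taking a `seed` argument never disturb the session RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single integer")
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

# Deterministic stream splitting: derive a sub-seed from a master seed and a
# stream offset, kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483587)
}

# Center each row and scale it to unit Euclidean norm.  Errors on rows with
# zero variance (their direction is undefined).
row_standardize <- function(x, what = "row") {
  x <- as.matrix(x)
  ctr <- x - rowMeans(x)
  nrm <- sqrt(rowSums(ctr^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stopf("%s %s has zero variance; cannot standardize", what, bad[1L])
  ctr / nrm
}

# A d x p matrix with orthonormal rows, each orthogonal to the constant
# vector.  Right-multiplying centered unit-norm latent rows by this matrix
# preserves their pairwise Pearson correlations exactly (the image rows have
# zero mean and unchanged inner products).  Requires p >= d + 1.
orthonormal_contrast <- function(d, p) {
  if (p < d + 1L)
    stopf("need at least %d output features to embed %d latent dimensions (got %d)",
          d + 1L, d, p)
  m <- cbind(rep(1, p), matrix(stats::rnorm(p * d), p, d))
  q <- qr.Q(qr(m))[, -1L, drop = FALSE]
  t(q)
}

# Map a conditions x d latent geometry to a conditions x p pattern matrix
# whose rows have zero mean, unit standard deviation, and pairwise Pearson
# correlations identical to those of the latent rows.
geometry_to_pattern <- function(geometry, p) {
  z <- row_standardize(geometry, "geometry row")
  x <- z %*% orthonormal_contrast(ncol(z), p)
  x * sqrt(p - 1)
}

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE)
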