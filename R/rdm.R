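#' Compute a representational dissimilarity matrix
#'
#' Entry (i, j) is `1 - Pearson(row_i, row_j)` of the condition pattern
#' matrix.  Because the Pearson correlation is a normalization-free ratio,
#' the result is invariant to per-condition affine maps `x -> a x + b`
#' (a > 0) of the pattern rows.
#'
#' @param patterns Conditions x features numeric matrix (>= 3 conditions).
#' @param labels Condition identifiers; defaults to the matrix row names.
#' @return An object of class `rdm`: a list with `matrix` (symmetric, zero
#'   diagonal, entries in `[0, 2]`) and `labels`.
#' @export
compute_rdm <- function(patterns, labels = rownames(patterns)) {
  patterns <- as.matrix(patterns)
  n <- nrow(patterns)
  if (n < 3) stopf("need >= 3 conditions to form an RDM (got %d)", n)
  if (is.null(labels)) labels <- default_condition_labels(n)
  v <- apply(patterns, 1L, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad))
    stopf("condition '%s' has a zero-variance (or non-finite) pattern vector",
          labels[bad[1L]])
  m <- 1 - stats::cor(t(patterns))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m <- pmin(pmax(m, 0), 2)
  dimnames(m) <- list(labels, labels)
  new_rdm(m, labels)
}

new_rdm <- function(matrix, labels) {
  structure(list(matrix = matrix, labels = as.character(labels)), class = "rdm")
}

#' Validate an RDM object
#' @param x An `rdm`.
#' @param tol Symmetry tolerance.
#' @return Invisibly `x`; errors if invariants are violated.
#' @export
validate_rdm <- function(x, tol = 1e-12) {
  if (!inherits(x, "rdm")) stopf("not an rdm object")
  m <- x$matrix
  if (nrow(m) != ncol(m)) stopf("RDM must be square")
  if (max(abs(m - t(m))) > tol) stopf("RDM is not symmetric (tolerance %g)", tol)
  if (any(abs(diag(m)) > tol)) stopf("RDM diagonal is not zero")
  if (any(m < -tol | m > 2 + tol)) stopf("RDM entries must lie in [0, 2]")
  invisible(x)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions; off-diagonal range [%.3f, %.3f]\n",
              nrow(x$matrix), min(x$matrix[upper.tri(x$matrix)]),
              max(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = "RDM", ...) {
  n <- nrow(x$matrix)
  graphics::image(seq_len(n), seq_len(n), t(x$matrix[n:1, ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "condition", ylab = "condition", main = main, ...)
  invisible(x)
}

#' Vectorize an RDM
#'
#' Returns the strictly-lower-triangle entries in row-major order
#' (equivalently, for a symmetric matrix, the upper triangle in column-major
#' order), length `n (n - 1) / 2`.  This ordering is shared by all modules
#' and by the serialization format.
#'
#' @param rdm An `rdm` object or a square symmetric matrix.
#' @return Numeric dissimilarity vector.
#' @export
vectorize_rdm <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else as.matrix(rdm)
  m[upper.tri(m)]
}

#' Reconstruct an RDM from its vectorized form
#'
#' Inverse of [vectorize_rdm()]: `devectorize_rdm(vectorize_rdm(r), r$labels)`
#' reproduces `r` exactly.
#'
#' @param v Dissimilarity vector of length `n (n - 1) / 2`.
#' @param labels Condition labels (length `n`); optional.
#' @return An `rdm` object.
#' @export
devectorize_rdm <- function(v, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9)
    stopf("vector length %d is not n(n-1)/2 for any integer n", length(v))
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  if (is.null(labels)) labels <- default_condition_labels(n)
  dimnames(m) <- list(labels, labels)
  new_rdm(m, labels)
}

#' Correlate two RDMs
#'
#' Pearson or Spearman correlation of the vectorized forms.  Spearman uses
#' average ranks for ties.
#'
#' @param a,b `rdm` objects over the same condition labels, or plain
#'   dissimilarity vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient.
#' @export
rdm_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(a, "rdm") && inherits(b, "rdm") && !identical(a$labels, b$labels))
    stopf("RDMs have different condition labels")
  va <- if (inherits(a, "rdm")) vectorize_rdm(a) else as.numeric(a)
  vb <- if (inherits(b, "rdm")) vectorize_rdm(b) else as.numeric(b)
  if (length(va) != length(vb)) stopf("dissimilarity vectors differ in length")
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stopf("correlation undefined for a constant dissimilarity vector")
  stats::cor(va, vb, method = method)
}

#' Build the RDM stack over a time-frequency grid
#'
#' Computes one RDM per signal kind and unmasked time-frequency coordinate
#' from condition pattern sets and stores its vectorized form as a row of a
#' coordinate x pair matrix.  Coordinates whose patterns are masked or
#' degenerate are kept as `NA` rows flagged invalid.
#'
#' @param ... One or more `pattern_set` objects (e.g. power and phase), as
#'   returned by [condition_power_patterns()] and
#'   [condition_phase_patterns()].
#' @return An object of class `rdm_stack`: `vectors` (coordinates x pairs),
#'   `index` (data frame with kind, freq_index, time_index, freq, time,
#'   valid), `labels`, `grid`, `n_conditions`.
#' @export
compute_rdm_stack <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "pattern_set"))
    sets <- sets[[1]]
  if (!length(sets)) stopf("no pattern sets supplied")
  for (s in sets) if (!inherits(s, "pattern_set"))
    stopf("all arguments must be pattern_set objects")
  grid <- sets[[1]]$grid
  labels <- sets[[1]]$conditions
  n <- length(labels)
  n_pairs <- n * (n - 1L) / 2L
  nf <- length(grid$freqs); nt <- length(grid$times)
  per_kind <- nf * nt
  vectors <- matrix(NA_real_, length(sets) * per_kind, n_pairs)
  valid_all <- logical(length(sets) * per_kind)
  n_failed <- 0L
  k <- 0L
  for (s in sets) {
    if (!identical(s$grid$freqs, grid$freqs) || !identical(s$grid$times, grid$times))
      stopf("pattern sets were computed on different grids")
    for (ti in seq_len(nt)) for (fi in seq_len(nf)) {
      k <- k + 1L
      if (!isTRUE(s$valid[fi, ti])) next
      pat <- s$values[, , fi, ti]
      if (!all(is.finite(pat))) next
      r <- tryCatch(compute_rdm(pat, labels = labels), error = function(e) NULL)
      if (is.null(r)) { n_failed <- n_failed + 1L; next }
      vectors[k, ] <- vectorize_rdm(r)
      valid_all[k] <- TRUE
    }
  }
  if (n_failed)
    warnf("%d coordinate(s) had degenerate patterns and were masked in the stack",
          n_failed)
  coords <- expand.grid(freq_index = seq_len(nf), time_index = seq_len(nt))
  idx <- data.frame(kind = rep(vapply(sets, `[[`, "", "kind"), each = per_kind),
                    freq_index = rep(coords$freq_index, length(sets)),
                    time_index = rep(coords$time_index, length(sets)),
                    stringsAsFactors = FALSE)
  idx$freq <- grid$freqs[idx$freq_index]
  idx$time <- grid$times[idx$time_index]
  idx$valid <- valid_all
  structure(list(vectors = vectors, index = idx, labels = labels, grid = grid,
                 n_conditions = n),
            class = "rdm_stack")
}

#' @export
print.rdm_stack <- function(x, ...) {
  cat(sprintf("<rdm_stack> %d coordinates (%d valid) x %d pairs; kinds: %s\n",
              nrow(x$vectors), sum(x$index$valid), ncol(x$vectors),
              paste(unique(x$index$kind), collapse = ", ")))
  invisible(x)
}
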