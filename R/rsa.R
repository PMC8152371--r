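#' Partial Pearson correlation
#'
#' Correlation between `x` and `y` after removing the linear contribution of
#' `z` from both:
#' `r = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param x,y,z Equal-length numeric vectors (length >= 4), none constant;
#'   `y` and `z` must not be collinear.
#' @return Partial correlation coefficient in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 4) stopf("need at least 4 observations for a partial correlation")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0)
    stopf("partial correlation undefined for constant input")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (1 - ryz^2 < 1e-12)
    stopf("y and z are collinear (|r| = %.6f); partial correlation undefined", abs(ryz))
  r <- (rxy - rxz * ryz) / sqrt(den)
  min(1, max(-1, r))
}

#' Partial-correlation RSA maps against a reference RDM pair
#'
#' At each valid stack coordinate, the partial Pearson correlation of the
#' coordinate's RDM vector with each reference RDM, controlling for the
#' other reference, is computed.  One map per signal kind and reference
#' target is returned (four maps for a power + phase stack).
#'
#' @param stack An `rdm_stack`.
#' @param ref_pair A `ref_rdm_pair` (or a list with `rdm_low`, `rdm_high`).
#' @return An object of class `rsa_maps`: `maps[[kind]][[target]]` with
#'   target `"low"` / `"high"`, each a freqs x times matrix (`NA` where
#'   masked), plus `grid`.
#' @export
rsa_map <- function(stack, ref_pair) {
  if (!inherits(stack, "rdm_stack")) stopf("`stack` must be an rdm_stack")
  v_low <- vectorize_rdm(ref_pair$rdm_low)
  v_high <- vectorize_rdm(ref_pair$rdm_high)
  if (length(v_low) != ncol(stack$vectors))
    stopf("reference RDMs have %d pairs but the stack has %d",
          length(v_low), ncol(stack$vectors))
  ryz <- stats::cor(v_low, v_high)
  if (1 - ryz^2 < 1e-12)
    stopf("the two reference RDMs are collinear (r = %.6f); partial correlation undefined",
          ryz)
  kinds <- unique(stack$index$kind)
  nf <- length(stack$grid$freqs); nt <- length(stack$grid$times)
  maps <- lapply(kinds, function(k)
    list(low = matrix(NA_real_, nf, nt), high = matrix(NA_real_, nf, nt)))
  names(maps) <- kinds
  n_failed <- 0L
  for (i in seq_len(nrow(stack$index))) {
    row <- stack$index[i, ]
    if (!row$valid) next
    x <- stack$vectors[i, ]
    res <- tryCatch(list(low = partial_correlation(x, v_low, v_high),
                         high = partial_correlation(x, v_high, v_low)),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    maps[[row$kind]]$low[row$freq_index, row$time_index] <- res$low
    maps[[row$kind]]$high[row$freq_index, row$time_index] <- res$high
  }
  if (n_failed)
    warnf("partial correlation failed at %d coordinate(s); masked in the RSA maps",
          n_failed)
  structure(list(maps = maps, grid = stack$grid), class = "rsa_maps")
}

#' @export
print.rsa_maps <- function(x, ...) {
  cat(sprintf("<rsa_maps> kinds: %s; targets: low, high; grid %d x %d\n",
              paste(names(x$maps), collapse = ", "),
              length(x$grid$freqs), length(x$grid$times)))
  invisible(x)
}

#' Group significance of subject-wise RSA maps
#'
#' One-sample t test of the per-subject partial correlations against zero at
#' every coordinate (on the raw r values by default, matching the original
#' procedure; set `fisher = TRUE` to test Fisher-z transformed values), with
#' two-sided p values and Benjamini-Hochberg FDR control across all
#' coordinates of the map at level `alpha`.  Coordinates masked in any
#' subject, or with zero variance across subjects, have undefined p and are
#' excluded from the FDR family (mask `FALSE`).
#'
#' @param maps List of freqs x times matrices, one per subject (>= 2), e.g.
#'   `lapply(subject_maps, function(m) m$maps$power$low)`.
#' @param alpha FDR level.
#' @param fisher Test Fisher-z transformed correlations instead of raw r.
#' @return An object of class `rsa_group_result`: `t_map`, `p_map`,
#'   `fdr_mask`, `alpha`, `n_subjects`.
#' @export
group_significance <- function(maps, alpha = 0.05, fisher = FALSE) {
  if (length(maps) < 2) stopf("need >= 2 subjects for a group test")
  dims <- dim(maps[[1]])
  arr <- vapply(maps, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), dims)) stopf("subject maps differ in grid size")
    m
  }, matrix(0, dims[1], dims[2]))
  if (fisher) arr <- atanh(pmin(pmax(arr, -1 + 1e-12), 1 - 1e-12))
  n <- length(maps)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  t_map <- mu / (sdv / sqrt(n))
  t_map[!is.finite(t_map)] <- NA_real_
  p_map <- 2 * stats::pt(-abs(t_map), df = n - 1)
  fdr_mask <- matrix(FALSE, dims[1], dims[2])
  ok <- is.finite(p_map)
  if (any(ok))
    fdr_mask[ok] <- stats::p.adjust(p_map[ok], method = "BH") <= alpha
  structure(list(t_map = t_map, p_map = p_map, fdr_mask = fdr_mask,
                 alpha = alpha, n_subjects = n),
            class = "rsa_group_result")
}

#' @export
print.rsa_group_result <- function(x, ...) {
  cat(sprintf("<rsa_group_result> n = %d subjects; %d/%d coordinates significant (BH, alpha = %g)\n",
              x$n_subjects, sum(x$fdr_mask), sum(is.finite(x$p_map)), x$alpha))
  invisible(x)
}

#' @export
plot.rsa_group_result <- function(x, grid = NULL, main = "group t map", ...) {
  fy <- if (is.null(grid)) seq_len(nrow(x$t_map)) else grid$freqs
  tx <- if (is.null(grid)) seq_len(ncol(x$t_map)) else grid$times
  graphics::image(tx, fy, t(x$t_map), col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "time (s)", ylab = "frequency (Hz)", main = main, ...)
  if (any(x$fdr_mask))
    graphics::contour(tx, fy, t(x$fdr_mask * 1), levels = 0.5, add = TRUE,
                      drawlabels = FALSE, col = "purple")
  invisible(x)
}

#' Latency-corrected time axis per frequency
#'
#' The sliding-window transform smears responses by half the window
#' duration; to avoid underestimating onset latencies, the time axis at
#' frequency f is shifted by `+ (window_cycles / f) / 2` seconds.  The
#' correction is monotone decreasing in frequency.
#'
#' @param grid A `tf_grid`.
#' @return A freqs x times matrix of corrected times;
#'   `attr(, "correction")` holds the per-frequency shift.
#' @export
latency_correct <- function(grid) {
  if (!inherits(grid, "tf_grid")) stopf("`grid` must be a tf_grid")
  corr <- (grid$window_cycles / grid$freqs) / 2
  out <- outer(corr, grid$times, "+")
  attr(out, "correction") <- corr
  out
}

#' Frequency-band time profile of a TF map
#'
#' Unweighted mean over the grid frequencies inside the closed band, per
#' time point.  The reported time axis is latency corrected by the mean
#' half-window duration of the contributing frequencies.
#'
#' @param map A freqs x times matrix (e.g. a subject RSA map or a group t
#'   map).
#' @param grid The `tf_grid` the map was computed on.
#' @param band Length-2 numeric `[f_lo, f_hi]` in Hz; must intersect the
#'   grid.  Canonical bands: alpha 8-13 Hz, low beta 13-20 Hz, high beta
#'   20-32 Hz.
#' @return Data frame with `time` (uncorrected), `time_corrected`, `value`.
#' @export
band_profile <- function(map, grid, band) {
  if (length(band) != 2L || band[1] > band[2]) stopf("`band` must be [f_lo, f_hi]")
  sel <- grid$freqs >= band[1] & grid$freqs <= band[2]
  if (!any(sel))
    stopf("band [%g, %g] Hz contains no grid frequency", band[1], band[2])
  m <- as.matrix(map)[sel, , drop = FALSE]
  value <- colMeans(m, na.rm = TRUE)
  value[colSums(is.finite(m)) == 0] <- NA_real_
  shift <- mean((grid$window_cycles / grid$freqs[sel]) / 2)
  data.frame(time = grid$times, time_corrected = grid$times + shift, value = value)
}
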