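#' Cortical-level score of a cluster centroid
#'
#' Combines the two partial correlations of a centroid with the low-level
#' (V1-like) and high-level (IT-like) reference RDMs into a single scale:
#' `L = sigmoid((R_high - R_low) / (R_high + R_low))`.
#'
#' The formula is implemented literally.  Note that for non-negative inputs
#' the ratio lies in `[-1, 1]`, so the attainable range of L is
#' approximately `[0.269, 0.731]` rather than the full `(0, 1)` interval;
#' `L = 0.5` means equal similarity to both references.  When
#' `R_high + R_low <= 0` the scale is undefined and an error is raised
#' (negative-sum inputs are not clamped).
#'
#' @param r_low Partial correlation with the low-level reference (R_V1).
#' @param r_high Partial correlation with the high-level reference (R_IT).
#' @return Level score L.  Swapping the arguments maps L to 1 - L.
#' @export
level_score <- function(r_low, r_high) {
  if (!is.finite(r_low) || !is.finite(r_high))
    stopf("level score requires finite partial correlations")
  s <- r_high + r_low
  if (s <= 0)
    stopf("level undefined: R_high + R_low = %.4f is not positive", s)
  stats::plogis((r_high - r_low) / s)
}

#' Surrogate permutation test for centroid-to-reference RSA
#'
#' The observed statistic is the partial correlation of `x` with `target`
#' controlling for `control`.  On each iteration the entries of `x` are
#' shuffled uniformly at random (`scheme = "entries"`, the literal reading
#' of shuffling the centroid RDM) or the condition labels of the RDM `x`
#' represents are permuted jointly over rows and columns
#' (`scheme = "labels"`, which preserves the RDM structure and is the
#' statistically stricter option), and the partial correlation is
#' recomputed.  The one-sided p value with add-one correction is
#' `(#\{surrogate >= observed\} + 1) / (n_iter + 1)`, so p is never zero and
#' never below `1/(n_iter + 1)`.
#'
#' @param x Centroid dissimilarity vector.
#' @param target Reference dissimilarity vector the observed correlation is
#'   computed against.
#' @param control Reference dissimilarity vector partialled out.
#' @param n_iter Number of surrogate iterations (default 1e5).
#' @param seed Integer seed; surrogate draws are reproducible given the
#'   seed.
#' @param scheme `"entries"` or `"labels"`.
#' @return An object of class `surrogate_test`: `p`, `observed`, `n_iter`,
#'   `scheme`.
#' @export
surrogate_test <- function(x, target, control, n_iter = 1e5, seed = 1,
                           scheme = c("entries", "labels")) {
  scheme <- match.arg(scheme)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) stopf("`n_iter` must be >= 1")
  x <- as.numeric(x); y <- as.numeric(target); z <- as.numeric(control)
  observed <- partial_correlation(x, y, z)
  n <- length(x)
  yc <- y - mean(y); zc <- z - mean(z)
  sy <- sqrt(sum(yc^2)); sz <- sqrt(sum(zc^2))
  ryz <- sum(yc * zc) / (sy * sz)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))          # invariant under permutation of entries
  if (scheme == "labels") {
    n_cond <- as.integer(round((1 + sqrt(1 + 8 * n)) / 2))
    if (n_cond * (n_cond - 1L) / 2L != n)
      stopf("`x` is not a vectorized RDM; the labels scheme needs n(n-1)/2 entries")
    xm <- devectorize_rdm(x)$matrix
  }
  exceed <- 0L
  chunk <- max(1L, min(n_iter, as.integer(2e6 / n)))
  with_seed(seed, {
    done <- 0L
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      if (scheme == "entries") {
        xp <- vapply(seq_len(m), function(i) xc[sample.int(n)], numeric(n))
      } else {
        xp <- vapply(seq_len(m), function(i) {
          p <- sample.int(n_cond)
          v <- xm[p, p][upper.tri(xm)]
          v - mean(v)
        }, numeric(n))
      }
      rxy <- as.numeric(crossprod(xp, yc)) / (sx * sy)
      rxz <- as.numeric(crossprod(xp, zc)) / (sx * sz)
      surr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      exceed <- exceed + sum(surr >= observed)
      done <- done + m
    }
  })
  structure(list(p = (exceed + 1) / (n_iter + 1), observed = observed,
                 n_iter = n_iter, scheme = scheme),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("<surrogate_test> observed partial r = %.4f, p = %.3g (%d iterations, %s scheme)\n",
              x$observed, x$p, x$n_iter, x$scheme))
  invisible(x)
}

#' Center layered features on an independent image set
#'
#' Subtracts, per layer, the per-feature mean of the centering set from the
#' analysis features.  This removes the common offset that places the
#' analysis images in a remote corner of feature space and would otherwise
#' distort correlation distances; because the centering images are disjoint
#' from the analysis images, no information leaks into the analysis RDMs.
#'
#' @param features A `layered_feature_set`.
#' @return The feature set with centered layers (`centered = TRUE`).
#' @export
center_features <- function(features) {
  if (!inherits(features, "layered_feature_set"))
    stopf("`features` must be a layered_feature_set")
  out <- features
  for (l in seq_len(features$n_layers)) {
    if (ncol(features$layers[[l]]) != ncol(features$centering[[l]]))
      stopf("layer %d: analysis and centering features have different widths", l)
    mu <- colMeans(features$centering[[l]])
    out$layers[[l]] <- sweep(features$layers[[l]], 2L, mu, "-")
  }
  out$centered <- TRUE
  out
}

#' Normalized distance of the image centroid to the feature-space origin
#'
#' Per layer: the Euclidean norm of the image-mean feature vector divided by
#' the root mean of the per-feature variances across images.  Large values
#' indicate that the image set sits far from the origin relative to its own
#' spread (the situation feature centering is designed to fix); a centered
#' cloud gives 0.
#'
#' @param features A `layered_feature_set` or a list of images x features
#'   matrices.
#' @return Numeric vector, one normalized distance per layer.
#' @export
centroid_origin_distance <- function(features) {
  layers <- if (inherits(features, "layered_feature_set")) features$layers
            else features
  vapply(seq_along(layers), function(l) {
    f <- as.matrix(layers[[l]])
    if (nrow(f) < 2) stopf("layer %d needs >= 2 images", l)
    v <- apply(f, 2L, stats::var)
    if (all(v == 0)) stopf("layer %d has zero feature variance", l)
    sqrt(sum(colMeans(f)^2)) / sqrt(mean(v))
  }, 0)
}

#' Feature-hierarchy complexity of a centroid
#'
#' For each hierarchy the centroid vector is compared (Spearman) with the
#' RDM of every centered layer; the best-matching layer index, normalized to
#' `[0, 1]` as `(argmax - 1) / (n_layers - 1)`, measures the complexity of
#' the representation (0 = first layer, 1 = last layer).  The mean position
#' across hierarchies is reported alongside the per-hierarchy scores.  Ties
#' at the argmax resolve to the smallest layer index (with a message).
#'
#' @param centroid Dissimilarity vector (e.g. a cluster centroid).
#' @param feature_sets List of `layered_feature_set` objects (uncentered
#'   sets are centered on their centering set first).
#' @return An object of class `complexity_score`: `per_hierarchy` (data
#'   frame with `hierarchy`, `argmax_layer`, `n_layers`, `position`,
#'   `peak_rho`) and `mean_position`.
#' @export
hierarchy_complexity <- function(centroid, feature_sets) {
  if (inherits(feature_sets, "layered_feature_set"))
    feature_sets <- list(feature_sets)
  centroid <- as.numeric(centroid)
  rows <- lapply(seq_along(feature_sets), function(h) {
    fs <- feature_sets[[h]]
    if (!inherits(fs, "layered_feature_set"))
      stopf("feature set %d is not a layered_feature_set", h)
    if (fs$n_layers < 2) stopf("hierarchy %d has fewer than 2 layers", h)
    if (!fs$centered) fs <- center_features(fs)
    rho <- vapply(seq_len(fs$n_layers), function(l) {
      v <- vectorize_rdm(compute_rdm(fs$layers[[l]]))
      rdm_correlation(v, centroid, method = "spearman")
    }, 0)
    amax <- which(rho == max(rho))
    if (length(amax) > 1L)
      message(sprintf("hierarchy %d: RSA tie at layers %s; taking the smallest",
                      h, paste(amax, collapse = ", ")))
    amax <- amax[1L]
    data.frame(hierarchy = h, argmax_layer = amax, n_layers = fs$n_layers,
               position = (amax - 1) / (fs$n_layers - 1), peak_rho = rho[amax])
  })
  per <- do.call(rbind, rows)
  structure(list(per_hierarchy = per, mean_position = mean(per$position)),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("<complexity_score> mean normalized position = %.3f over %d hierarchies\n",
              x$mean_position, nrow(x$per_hierarchy)))
  print(x$per_hierarchy, row.names = FALSE)
  invisible(x)
}

#' Level and significance scores for all cluster centroids
#'
#' For each centroid of a cluster result: the partial correlations with the
#' low and high reference RDMs (each controlling the other), the cortical
#' level score L, and one-sided surrogate p values for both references.
#' Centroids with a non-positive `R_low + R_high` get `NA` level (with a
#' warning) rather than a clamped value.
#'
#' @param result A `cluster_result`.
#' @param ref_pair A `ref_rdm_pair`.
#' @param n_iter Surrogate iterations per test.
#' @param seed Integer seed.
#' @param scheme Surrogate scheme, see [surrogate_test()].
#' @return Data frame with `cluster`, `r_low`, `r_high`, `level`, `p_low`,
#'   `p_high`.
#' @export
cluster_level_scores <- function(result, ref_pair, n_iter = 1e4, seed = 1,
                                 scheme = "entries") {
  v_low <- vectorize_rdm(ref_pair$rdm_low)
  v_high <- vectorize_rdm(ref_pair$rdm_high)
  k <- nrow(result$centroids)
  out <- lapply(seq_len(k), function(j) {
    cen <- result$centroids[j, ]
    r_low <- partial_correlation(cen, v_low, v_high)
    r_high <- partial_correlation(cen, v_high, v_low)
    lv <- tryCatch(level_score(r_low, r_high), error = function(e) {
      warnf("cluster %d: %s", j, conditionMessage(e)); NA_real_
    })
    p_lo <- surrogate_test(cen, v_low, v_high, n_iter = n_iter,
                           seed = derive_seed(seed, 2L * j), scheme = scheme)$p
    p_hi <- surrogate_test(cen, v_high, v_low, n_iter = n_iter,
                           seed = derive_seed(seed, 2L * j + 1L), scheme = scheme)$p
    data.frame(cluster = j, r_low = r_low, r_high = r_high, level = lv,
               p_low = p_lo, p_high = p_hi)
  })
  do.call(rbind, out)
}
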