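# Row-center and unit-normalize vectors for correlation distance:
# 1 - Pearson(x, y) = 1 - xn . yn after this transform.
corr_normalize <- function(x) {
  x <- as.matrix(x)
  ctr <- x - rowMeans(x)
  nrm <- sqrt(rowSums(ctr^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stopf("vector %d is constant; correlation distance undefined", bad[1L])
  ctr / nrm
}

#' Correlation-distance k-means
#'
#' Lloyd iterations under the correlation distance: each vector is
#' row-centered and unit-normalized, points are assigned to the centroid
#' with the smallest `1 - Pearson` distance, and each centroid is updated to
#' the renormalized mean of its members.  An empty cluster is re-seeded from
#' the point farthest from its current centroid.  The best of `replicates`
#' random initializations (lowest residual sum of distances, RSS) is kept;
#' the whole procedure is deterministic given `seed`.
#'
#' @param vectors Points x dimensions numeric matrix (e.g. stacked RDM
#'   vectors); no row may be constant.
#' @param k Number of clusters (1 <= k <= number of points).
#' @param replicates Number of random restarts.
#' @param seed Integer seed.
#' @param max_iter Iteration cap per replicate.
#' @return List with `assignments`, `centroids` (k x dims, centered and
#'   unit-normalized), `rss`, `k`, `iterations`.
#' @export
kmeans_rdm <- function(vectors, k, replicates = 5, seed = 1, max_iter = 100) {
  xn <- corr_normalize(vectors)
  n <- nrow(xn)
  if (k < 1 || k > n) stopf("`k` must be in 1..%d", n)
  with_seed(seed, {
    best <- NULL
    for (rep_i in seq_len(replicates)) {
      cen <- xn[sample.int(n, k), , drop = FALSE]
      assign_old <- rep(0L, n)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        sim <- xn %*% t(cen)                      # Pearson similarity to centroids
        assign_new <- max.col(sim, ties.method = "first")
        for (j in seq_len(k)) {
          if (!any(assign_new == j)) {            # empty cluster: re-seed from the
            d_own <- 1 - sim[cbind(seq_len(n), assign_new)]
            sizes <- tabulate(assign_new, k)      # farthest point whose donor
            movable <- sizes[assign_new] > 1L     # cluster keeps >= 1 member
            far <- which(movable)[which.max(d_own[movable])]
            assign_new[far] <- j
          }
        }
        if (identical(assign_new, assign_old) || iter >= max_iter) {
          assign_old <- assign_new
          break
        }
        assign_old <- assign_new
        for (j in seq_len(k)) {
          mu <- colMeans(xn[assign_new == j, , drop = FALSE])
          mu <- mu - mean(mu)
          nm <- sqrt(sum(mu^2))
          if (nm > 0) cen[j, ] <- mu / nm
        }
      }
      sim <- xn %*% t(cen)
      rss <- sum(1 - sim[cbind(seq_len(n), assign_old)])
      if (is.null(best) || rss < best$rss)
        best <- list(assignments = assign_old, centroids = cen, rss = rss,
                     k = as.integer(k), iterations = iter)
    }
    best
  })
}

#' Choose the cluster count by the elbow criterion
#'
#' The discrete second derivative of the RSS curve,
#' `d2(k) = RSS(k+1) - 2 RSS(k) + RSS(k-1)`, is evaluated on the centered
#' k grid `2..K-1` and the elbow is located at its (positive) maximum
#' `k_m`, with exact ties broken toward the smallest k.  At `k_m` the RSS
#' gain from adding one more cluster collapses, so `rule = "at"` (the
#' default) returns `k_m`; this is the reading under which the criterion
#' recovers the planted family count on stacks with a sharp RSS kink (the
#' kink at the true count k0 has its centered second difference at k0).
#' `rule = "before"` returns `k_m - 1`, the literal "point just before the
#' maximum" on the centered grid; see the methods vignette for why the two
#' readings differ by one index.  A curve with no positive curvature (e.g.
#' exactly linear) raises a "no elbow" error.
#'
#' @param rss_curve Numeric RSS values for k = 1..K (K >= 4).
#' @param rule `"at"` (default) or `"before"`.
#' @return Integer `k*`.
#' @export
choose_k_elbow <- function(rss_curve, rule = c("at", "before")) {
  rule <- match.arg(rule)
  K <- length(rss_curve)
  if (K < 4) stopf("need an RSS curve over at least k = 1..4")
  ks <- 2:(K - 1)
  d2 <- rss_curve[ks + 1] - 2 * rss_curve[ks] + rss_curve[ks - 1]
  tol <- 1e-10 * max(abs(rss_curve), 1)
  if (all(d2 <= tol))
    stopf("no elbow: the RSS curve has no positive curvature maximum")
  k_m <- ks[which.max(d2)]
  if (rule == "before") max(1L, k_m - 1L) else k_m
}

#' Cluster an RDM stack with model selection
#'
#' Runs [kmeans_rdm()] on the valid coordinates of an RDM stack (or a plain
#' matrix of vectors) for `k = 1..kmax` and selects the cluster count with
#' [choose_k_elbow()].
#'
#' @param stack An `rdm_stack` or a points x dimensions matrix.
#' @param kmax Largest cluster count to try.
#' @param replicates Random restarts per k.
#' @param seed Integer seed.
#' @param rule Elbow rule, see [choose_k_elbow()].
#' @return An object of class `cluster_result`: `assignments` (integer per
#'   valid coordinate), `centroids`, `rss_curve`, `chosen_k`, `replicates`,
#'   `seed`, `index` (coordinate index with an `assignment` column when a
#'   stack was supplied).
#' @export
cluster_rdm_stack <- function(stack, kmax = 20, replicates = 5, seed = 1,
                              rule = c("at", "before")) {
  rule <- match.arg(rule)
  idx <- NULL
  if (inherits(stack, "rdm_stack")) {
    vectors <- stack$vectors[stack$index$valid, , drop = FALSE]
    idx <- stack$index
  } else vectors <- as.matrix(stack)
  kmax <- min(kmax, nrow(vectors))
  rss_curve <- numeric(kmax)
  fits <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    fits[[k]] <- kmeans_rdm(vectors, k, replicates = replicates,
                            seed = derive_seed(seed, k))
    rss_curve[k] <- fits[[k]]$rss
  }
  chosen_k <- choose_k_elbow(rss_curve, rule = rule)
  fit <- fits[[chosen_k]]
  if (!is.null(idx)) {
    idx$assignment <- NA_integer_
    idx$assignment[idx$valid] <- fit$assignments
  }
  structure(list(assignments = fit$assignments, centroids = fit$centroids,
                 rss_curve = rss_curve, chosen_k = chosen_k,
                 replicates = replicates, seed = seed, rule = rule,
                 index = idx),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k = %d (rule '%s'); RSS(k*) = %.4f; sizes: %s\n",
              x$chosen_k, x$rule, x$rss_curve[x$chosen_k],
              paste(tabulate(x$assignments, x$chosen_k), collapse = ", ")))
  invisible(x)
}

#' Distance-to-centroid time-frequency maps
#'
#' For each cluster and each signal kind, the correlation distance between
#' every coordinate's RDM vector and the cluster centroid, arranged as a
#' freqs x times map (`NA` where masked).  Distances lie in `[0, 2]`.
#'
#' @param result A `cluster_result` fitted on `stack`.
#' @param stack The `rdm_stack` that was clustered.
#' @return An object of class `centroid_distance_maps`: a list (one element
#'   per cluster) of lists of freqs x times matrices, one per signal kind.
#' @export
distance_to_centroid_maps <- function(result, stack) {
  if (!inherits(stack, "rdm_stack")) stopf("`stack` must be an rdm_stack")
  xn <- corr_normalize(stack$vectors[stack$index$valid, , drop = FALSE])
  sim <- xn %*% t(result$centroids)        # valid coords x k
  kinds <- unique(stack$index$kind)
  nf <- length(stack$grid$freqs); nt <- length(stack$grid$times)
  vi <- which(stack$index$valid)
  out <- lapply(seq_len(result$chosen_k %||% ncol(sim)), function(j) {
    per_kind <- lapply(kinds, function(kd) matrix(NA_real_, nf, nt))
    names(per_kind) <- kinds
    for (m in seq_along(vi)) {
      row <- stack$index[vi[m], ]
      per_kind[[row$kind]][row$freq_index, row$time_index] <- 1 - sim[m, j]
    }
    per_kind
  })
  structure(list(maps = out, grid = stack$grid), class = "centroid_distance_maps")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank clusters by compactness
#'
#' Orders cluster ids by ascending mean member-to-centroid correlation
#' distance, so the most stereotyped (tightest) cluster ranks first.
#'
#' @param result A `cluster_result`.
#' @param stack The clustered `rdm_stack` (or the matrix of vectors used).
#' @return Data frame with `cluster`, `mean_distance`, `size`, ordered by
#'   rank.
#' @export
rank_clusters <- function(result, stack) {
  vectors <- if (inherits(stack, "rdm_stack"))
    stack$vectors[stack$index$valid, , drop = FALSE] else as.matrix(stack)
  xn <- corr_normalize(vectors)
  sim <- xn %*% t(result$centroids)
  d_own <- 1 - sim[cbind(seq_len(nrow(xn)), result$assignments)]
  k <- nrow(result$centroids)
  md <- vapply(seq_len(k), function(j) mean(d_own[result$assignments == j]), 0)
  sz <- tabulate(result$assignments, k)
  out <- data.frame(cluster = seq_len(k), mean_distance = md, size = sz)
  out[order(out$mean_distance), ]
}
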