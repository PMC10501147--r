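#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution:
#' each column's sorted values are replaced by the across-column means
#' of the sorted values, ties receiving the mean of their would-be
#' positions. Delegates to the standard limma implementation. The
#' operation is idempotent; a single-column matrix is returned
#' unchanged with a warning.
#'
#' @param m Numeric matrix (probes x samples), no fully-missing column.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(colSums(!is.na(m)) == 0))
    stop("fully-missing column: cannot quantile-normalize")
  if (ncol(m) < 2L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' K-means clustering QC of an expression dataset
#'
#' Clusters samples (points in the subspace of the `n_top` most
#' variable probes, optionally after quantile normalization) with
#' multi-start Lloyd k-means, reports the within-group sum-of-squares
#' (WSS) curve over `k = 1..k_max`, an elbow estimate of the optimal k
#' (maximum second difference of the curve), and the chance-corrected
#' agreement (adjusted Rand index) between the `k`-cluster assignment
#' and the tumor/control labels. For `k = 1` the agreement is 0 by
#' convention and the WSS equals the total sum of squares. In addition
#' to random starts, each `k` is seeded from the best `k - 1` solution
#' with its widest cluster split, which makes the reported WSS curve
#' non-increasing in k.
#'
#' @param ds An [expression_dataset()].
#' @param k Number of clusters for the reported assignment (default 2,
#'   the tumor/control question).
#' @param k_max Largest k of the WSS curve.
#' @param n_init Random starts per k (default 10).
#' @param n_top Number of top-variance probes to cluster on (default
#'   2000).
#' @param normalize Quantile-normalize first (default `FALSE`).
#' @param seed Integer seed.
#' @return An object of class `cluster_report`: `k`, `assignment`
#'   (named by sample), `agreement`, `wss` (named numeric over
#'   `1..k_max`), `optimal_k`, `coords` (samples x probes matrix used).
#' @export
kmeans_cluster <- function(ds, k = 2L, k_max = 8L, n_init = 10L,
                           n_top = 2000L, normalize = FALSE, seed = 1L) {
  stopifnot(inherits(ds, "expr_dataset"))
  n <- ncol(ds$values)
  if (k > n) stop("k exceeds the number of samples")
  k_max <- min(k_max, n)
  m <- ds$values
  if (normalize) m <- quantile_normalize(m)
  v <- apply(m, 1L, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(m)))]
  x <- t(m[top, , drop = FALSE])

  set.seed(seed)
  fits <- vector("list", k_max)
  fits[[1]] <- list(cluster = rep(1L, n),
                    centers = matrix(colMeans(x), 1L),
                    tot.withinss = sum(scale(x, scale = FALSE)^2))
  for (kk in seq(2L, length.out = max(0L, k_max - 1L))) {
    best <- suppressWarnings(
      stats::kmeans(x, centers = kk, nstart = n_init,
                    algorithm = "Lloyd", iter.max = 100L))
    # warm start: split the widest cluster of the best (k-1) solution
    prev <- fits[[kk - 1L]]
    wss_per <- vapply(seq_len(kk - 1L), function(cl) {
      pts <- x[prev$cluster == cl, , drop = FALSE]
      sum(sweep(pts, 2L, colMeans(pts))^2)
    }, 0)
    widest <- which.max(wss_per)
    pts <- x[prev$cluster == widest, , drop = FALSE]
    ctr <- colMeans(pts)
    far <- pts[which.max(rowSums(sweep(pts, 2L, ctr)^2)), ]
    centers <- rbind(prev$centers, far)
    warm <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     algorithm = "Lloyd",
                                     iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(warm) && warm$tot.withinss < best$tot.withinss)
      best <- warm
    fits[[kk]] <- best
  }
  wss <- vapply(fits, `[[`, 0, "tot.withinss")
  names(wss) <- seq_len(k_max)
  optimal_k <- if (k_max >= 3L) {
    d2 <- diff(diff(wss))                # second difference ("elbow")
    as.integer(which.max(d2) + 1L)
  } else NA_integer_

  assignment <- stats::setNames(fits[[k]]$cluster, colnames(ds$values))
  agreement <- if (k == 1L) 0 else
    mclust::adjustedRandIndex(assignment, ds$group)

  structure(list(k = k, assignment = assignment, agreement = agreement,
                 wss = wss, optimal_k = optimal_k,
                 dataset_id = ds$dataset_id),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Cluster report [%s]: k = %d\n", x$dataset_id, x$k))
  cat(sprintf("  agreement with tumor/control labels (adjusted Rand): %.3f\n",
              x$agreement))
  cat(sprintf("  elbow estimate of optimal k: %s\n",
              ifelse(is.na(x$optimal_k), "n/a", x$optimal_k)))
  cat("  WSS: ", paste(sprintf("%.3g", x$wss), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
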