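#' Select a marker feature matrix from a cell table
#'
#' Restricts the per-cell mean-expression columns to a marker list, in the
#' given order, on raw values (display normalization is applied only when
#' plotting). The canonical monocyte/macrophage list is CD14, CD16, CD68,
#' CD163, P2Y12, CC3, Ki67, CD40, CD206, HIF1a, MMP9, MPO, OX40L, pSTAT3.
#'
#' @param cells a [cell_table()].
#' @param markers character vector of marker names.
#' @return Numeric matrix cells x markers.
#' @export
select_features <- function(cells, markers) {
  cols <- paste0("expr_", markers)
  missing <- setdiff(cols, names(cells))
  if (length(missing))
    stop("markers absent from cell table: ",
         paste(sub("^expr_", "", missing), collapse = ", "), call. = FALSE)
  m <- as.matrix(as.data.frame(cells)[cols])
  colnames(m) <- markers
  m
}

#' t-SNE embedding
#'
#' Exact (non-approximated) t-SNE with the standard defaults: perplexity
#' 30, early exaggeration 12 for the first quarter of iterations, momentum
#' 0.5 rising to 0.8, adaptive gains. Quadratic in the number of cells, so
#' intended for subsets up to a few thousand cells; deterministic given
#' `seed`.
#'
#' @param X feature matrix (cells x markers).
#' @param seed RNG seed.
#' @param perplexity target perplexity; requires `nrow(X) >= 3 * perplexity + 1`.
#' @param n_iter gradient-descent iterations; default 500.
#' @param eta learning rate; default 200.
#' @return Numeric matrix cells x 2.
#' @export
tsne_embed <- function(X, seed = 0L, perplexity = 30, n_iter = 500L,
                       eta = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3 * perplexity + 1)
    stop("too few cells for perplexity ", perplexity,
         " (need at least ", 3 * perplexity + 1, ")", call. = FALSE)
  D2 <- cross_dist2(X, X)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  local_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    exag <- ceiling(n_iter / 4)
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= exag) P * 12 else P
      num <- 1 / (1 + cross_dist2(Y, Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      G <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it < 250) 0.5 else 0.8
      gains <- ifelse(sign(G) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- mom * inc - eta * gains * G
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' DBSCAN density clustering
#'
#' Classic DBSCAN: a point is a core point when at least `min_pts` points
#' (including itself) lie within `eps`; clusters are the connected
#' components of core points, border points join the first cluster that
#' reaches them, remaining points are noise (label 0). Deterministic
#' (scan order by point index).
#'
#' @param X coordinate matrix (points x dims); typically 2-D embedding
#'   coordinates with `eps = 3`, `min_pts = 30`.
#' @param eps neighbourhood radius.
#' @param min_pts core-point threshold.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
dbscan_points <- function(X, eps = 3, min_pts = 30L) {
  X <- as.matrix(X)
  n <- nrow(X)
  # neighbour lists within eps (self excluded), chunked
  nb <- vector("list", n)
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    d2 <- cross_dist2(X[rows, , drop = FALSE], X)
    for (r in seq_along(rows)) {
      i <- rows[r]
      w <- which(d2[r, ] <= eps^2)
      nb[[i]] <- w[w != i]
    }
  }
  core <- vapply(nb, length, integer(1)) + 1L >= min_pts
  lab <- rep.int(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (lab[j] == 0L) {
        lab[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][lab[nb[[j]]] == 0L])
      }
    }
  }
  lab
}

#' Spectral clustering on a kNN affinity graph
#'
#' Symmetric kNN affinity (points connected when either is among the
#' other's `knn` nearest), symmetric-normalized Laplacian, top-`k`
#' eigenvector embedding with row normalization, k-means on the embedding
#' (deterministic given `seed`).
#'
#' @param X coordinate matrix.
#' @param k number of clusters.
#' @param knn affinity-graph neighbour count; default 15.
#' @param seed RNG seed for the final k-means.
#' @return Integer cluster labels (1..k).
#' @export
spectral_cluster <- function(X, k, knn = 15L, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of points", call. = FALSE)
  knn <- min(knn, n - 1L)
  d2 <- cross_dist2(X, X)
  diag(d2) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    o <- order(d2[i, ])[seq_len(knn)]
    A[i, o] <- 1
  }
  A <- pmax(A, t(A))  # symmetric union
  d <- pmax(rowSums(A), 1e-12)
  S <- A / sqrt(d) / rep(sqrt(d), each = n)  # D^-1/2 A D^-1/2
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  local_seed(seed, kmeans(U, centers = k, nstart = 10, iter.max = 100)$cluster)
}

#' Hybrid density / spectral clustering with kNN label extension
#'
#' The composite clustering procedure for large phenotype embeddings:
#' (i) DBSCAN (defaults eps 3, min_pts 30) isolates similar-density
#' clusters; (ii) every DBSCAN cluster except the largest is kept as a
#' final "small" cluster, while the largest forms the "big" group;
#' (iii) the big group is subsampled 1-in-`subsample_rate` and the
#' subsample is re-clustered by [spectral_cluster()] into `n_spectral`
#' clusters; (iv) a k-nearest-neighbour classifier (`knn_k = 5`) trained
#' on all labelled points (small clusters plus the labelled subsample)
#' assigns final labels to every remaining point, so the labelling is
#' total. Labelled points keep their labels, which makes the extension
#' step idempotent. If DBSCAN marks everything noise, all points fall back
#' to a single cluster with a warning.
#'
#' @param X coordinate matrix (typically 2-D t-SNE coordinates).
#' @param n_spectral number of spectral clusters for the big group; use 1
#'   to keep the big group intact.
#' @param eps,min_pts DBSCAN parameters.
#' @param subsample_rate take 1 in this many points of the big group;
#'   default 10.
#' @param knn_k neighbours for the final classifier; default 5.
#' @param seed RNG seed.
#' @return Integer vector of final cluster labels (1-based, every point
#'   labelled).
#' @export
hybrid_cluster <- function(X, n_spectral, eps = 3, min_pts = 30L,
                           subsample_rate = 10L, knn_k = 5L, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < min_pts)
    stop("fewer points than min_pts", call. = FALSE)
  db <- dbscan_points(X, eps = eps, min_pts = min_pts)
  if (all(db == 0L)) {
    warning("DBSCAN found no dense cluster; falling back to one cluster")
    return(rep.int(1L, n))
  }
  sizes <- tabulate(db[db > 0L])
  big <- which.max(sizes)
  lab <- rep.int(NA_integer_, n)
  small_ids <- setdiff(which(sizes > 0), big)
  next_lab <- 0L
  for (s in small_ids) {
    next_lab <- next_lab + 1L
    lab[db == s] <- next_lab
  }
  big_idx <- which(db == big)
  sub <- local_seed(derive_seed(seed, "subsample"), {
    m <- max(1L, floor(length(big_idx) / subsample_rate))
    sort(sample(big_idx, m))
  })
  if (n_spectral <= 1 || length(sub) <= n_spectral) {
    lab[sub] <- next_lab + 1L
    next_lab <- next_lab + 1L
  } else {
    sp <- spectral_cluster(X[sub, , drop = FALSE], n_spectral,
                           seed = derive_seed(seed, "spectral"))
    lab[sub] <- next_lab + sp
    next_lab <- next_lab + n_spectral
  }
  lab <- knn_extend(X, lab, k = knn_k, seed = derive_seed(seed, "knn"))
  lab
}

#' @rdname hybrid_cluster
#' @param labels partial labels (`NA` = unlabelled); labelled points are
#'   never changed.
#' @return [knn_extend()] returns the completed label vector.
#' @export
knn_extend <- function(X, labels, k = 5L, seed = 0L) {
  train <- which(!is.na(labels))
  test <- which(is.na(labels))
  if (!length(train)) stop("no labelled points to extend from", call. = FALSE)
  if (!length(test)) return(labels)
  pred <- local_seed(seed, {
    class::knn(X[train, , drop = FALSE], X[test, , drop = FALSE],
               factor(labels[train]), k = min(k, length(train)))
  })
  labels[test] <- as.integer(as.character(pred))
  labels
}

#' Cluster-mean marker heatmap matrix
#'
#' Per marker: normalize expression to its 95th percentile (display
#' convention), average within clusters, then z-score the cluster means
#' across clusters, so each marker column sums to zero. With a single
#' cluster the raw normalized means are returned with a warning.
#'
#' @param features cells x markers matrix (raw values).
#' @param labels cluster label per cell.
#' @param pct normalization percentile; default 95.
#' @return Matrix clusters x markers of z-scored means.
#' @export
cluster_heatmap <- function(features, labels, pct = 95) {
  features <- as.matrix(features)
  norm <- apply(features, 2, normalize_for_display, pct = pct)
  means <- rowsum(norm, labels) / as.vector(table(labels))
  if (nrow(means) < 2) {
    warning("single cluster: z-scores undefined, returning raw means")
    return(means)
  }
  zscore_cluster_means(means)
}
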