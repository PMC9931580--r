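#' Nearest-neighbour composition windows
#'
#' For every cell of an image, the window is the frequency vector of the
#' types of its `N` nearest other cells (Euclidean centroid distance; the
#' index cell itself is excluded unless `include_self = TRUE`). Ties at
#' the N-th distance are broken by cell order for reproducibility. Images
#' with at most `N` cells use all other cells and are flagged.
#'
#' @param x,y centroid coordinates (um).
#' @param types cell-type labels (character/factor); `"Undefined"` counts
#'   as its own type.
#' @param N window size; default 10.
#' @param type_levels the full type alphabet the frequency vector spans;
#'   default the sorted unique types.
#' @param include_self include the index cell in its own window.
#' @return Matrix cells x types of frequencies (rows sum to 1), with
#'   attributes `N` and `truncated` (TRUE when fewer than N neighbours
#'   were available).
#' @export
neighbour_windows <- function(x, y, types, N = 10L, type_levels = NULL,
                              include_self = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, length(types) == n, n >= 2)
  tch <- as.character(types)
  if (is.null(type_levels)) type_levels <- sort(unique(tch))
  ti <- match(tch, type_levels)
  if (anyNA(ti)) stop("types outside type_levels", call. = FALSE)
  avail <- if (include_self) n else n - 1L
  Nuse <- min(N, avail)
  W <- matrix(0, n, length(type_levels),
              dimnames = list(NULL, type_levels))
  # chunked distance computation keeps memory bounded for big images
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[rows]^2 + y[rows]^2, x^2 + y^2, "+") -
      2 * (outer(x[rows], x) + outer(y[rows], y))
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- d2[r, ]
      if (!include_self) d[i] <- Inf
      o <- order(d, seq_len(n))[seq_len(Nuse)]
      W[i, ] <- tabulate(ti[o], nbins = length(type_levels)) / Nuse
    }
  }
  attr(W, "N") <- N
  attr(W, "truncated") <- Nuse < N
  W
}

#' Mini-batch k-means
#'
#' Sculley-style mini-batch k-means with k-means++ seeding: at each
#' iteration a random batch is assigned to its nearest centres and every
#' centre moves to the running mean of all samples ever assigned to it
#' (per-centre learning rate `1/count`). Deterministic given `seed` and
#' the input row order. Iteration stops after `max_iter` batches or when
#' the largest centre displacement falls below `tol`.
#'
#' @param X numeric matrix (samples x features).
#' @param k number of clusters.
#' @param batch_size samples per batch; default 100.
#' @param seed RNG seed; default 0.
#' @param max_iter maximum number of batches; default 100.
#' @param tol convergence tolerance on centre movement; default 1e-6.
#' @return List with `centers` (k x features) and `cluster` (nearest-centre
#'   label per row of `X`).
#' @export
minibatch_kmeans <- function(X, k, batch_size = 100L, seed = 0L,
                             max_iter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k == 1)  # closed form: the optimum is the grand mean
    return(list(centers = matrix(colMeans(X), 1,
                                 dimnames = list(NULL, colnames(X))),
                cluster = rep.int(1L, n)))
  local_seed(seed, {
    centers <- X[kmeanspp_init(X, k), , drop = FALSE]
    counts <- rep.int(0, k)
    for (it in seq_len(max_iter)) {
      b <- sample.int(n, min(batch_size, n))
      d2 <- cross_dist2(X[b, , drop = FALSE], centers)
      a <- max.col(-d2, ties.method = "first")
      old <- centers
      for (c in unique(a)) {
        rows <- b[a == c]
        m <- length(rows)
        centers[c, ] <- (counts[c] * centers[c, ] +
                           colSums(X[rows, , drop = FALSE])) / (counts[c] + m)
        counts[c] <- counts[c] + m
      }
      if (max(abs(centers - old)) < tol) break
    }
    d2 <- cross_dist2(X, centers)
    list(centers = centers, cluster = max.col(-d2, ties.method = "first"))
  })
}

#' Fit a cellular-neighbourhood model
#'
#' Pools the windows of the discovery images and clusters them into `K`
#' cellular neighbourhoods (CNs) with [minibatch_kmeans()] (defaults:
#' batch size 100, seed 0); every
#' cell is then assigned the CN of its nearest centroid. Margin-type
#' images can be excluded from discovery and assigned afterwards with
#' [predict_cn()].
#'
#' @param windows matrix of window frequency vectors (rows = cells),
#'   e.g. stacked [neighbour_windows()] outputs sharing a type alphabet.
#' @param K number of neighbourhoods (9 is a common coarse choice for
#'   tissue niches; 30 resolves finer structure).
#' @param seed RNG seed; default 0.
#' @param batch_size mini-batch size; default 100.
#' @return Object of class `cn_model`: list with `centers`, `labels`
#'   (CN per input row, in 1..K), `K`, `N` (window size attribute if
#'   present), `seed`, `batch_size`.
#' @export
fit_cn <- function(windows, K, seed = 0L, batch_size = 100L) {
  if (K > nrow(windows))
    stop("K exceeds the number of windows", call. = FALSE)
  fit <- minibatch_kmeans(windows, K, batch_size = batch_size, seed = seed)
  structure(list(centers = fit$centers, labels = fit$cluster, K = K,
                 N = attr(windows, "N"), seed = seed,
                 batch_size = batch_size),
            class = "cn_model")
}

#' @rdname fit_cn
#' @param model a fitted `cn_model`.
#' @param newwindows windows to assign (same type alphabet/column order).
#' @return [predict_cn()] returns integer CN labels.
#' @export
predict_cn <- function(model, newwindows) {
  d2 <- cross_dist2(as.matrix(newwindows), model$centers)
  max.col(-d2, ties.method = "first")
}

#' @export
print.cn_model <- function(x, ...) {
  cat(sprintf("cn_model: K = %d neighbourhoods, %d cells, seed %d, batch %d\n",
              x$K, length(x$labels), x$seed, x$batch_size))
  invisible(x)
}

#' Per-image CN prevalence and cohort z-scores
#'
#' The prevalence of each CN in an image is its share of the image's
#' cells, normalized so each image's prevalences sum to 100 percent;
#' cohort z-scores are computed per CN across images. Patient-level
#' prevalence (duplicate cores averaged) is obtained by passing the
#' percentage table through [average_by_patient()].
#'
#' @param image_id image id per cell.
#' @param cn integer CN label per cell (1..K).
#' @param K number of neighbourhoods.
#' @return List with `percent` (images x K matrix, rows sum to 100) and
#'   `zscore` (same shape, z-scored within each CN column).
#' @export
cn_prevalence <- function(image_id, cn, K) {
  stopifnot(length(image_id) == length(cn))
  tab <- table(image_id, factor(cn, levels = seq_len(K)))
  pct <- sweep(unclass(tab), 1, rowSums(tab), "/") * 100
  zs <- apply(pct, 2, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep.int(0, length(v)) else (v - mean(v)) / s
  })
  if (is.null(dim(zs))) zs <- matrix(zs, nrow = 1, dimnames = dimnames(pct))
  list(percent = pct, zscore = zs)
}

#' Stratify patients by CN prevalence
#'
#' Splits patients (or images) into a high and a low group on one CN's
#' prevalence, either by cohort z-score (high: z >= 0) or by median
#' (high: value >= median). Degenerate input (all values identical) puts
#' everyone in the high group with a warning.
#'
#' @param prevalence numeric vector of per-patient prevalences (percent),
#'   named by patient.
#' @param split `"zscore"` (default) or `"median"`.
#' @return Factor with levels `low`, `high`, same length/names as
#'   `prevalence`.
#' @export
stratify_by_cn <- function(prevalence, split = c("zscore", "median")) {
  split <- match.arg(split)
  if (sd(prevalence) == 0 || is.na(sd(prevalence))) {
    warning("degenerate prevalence: all values identical; single group")
    g <- rep.int("high", length(prevalence))
  } else if (split == "zscore") {
    z <- (prevalence - mean(prevalence)) / sd(prevalence)
    g <- ifelse(z >= 0, "high", "low")
  } else {
    g <- ifelse(prevalence >= median(prevalence), "high", "low")
  }
  factor(setNames(g, names(prevalence)), levels = c("low", "high"))
}

#' Discrete Voronoi rendering of CN labels
#'
#' Projects per-cell CN labels onto the image plane as a Voronoi
#' tessellation: every pixel takes the CN of its nearest cell centroid,
#' clipped to the image bounds. Exactly collinear degenerate inputs are
#' jittered (with a warning) to keep the tessellation well defined.
#'
#' @param x,y cell centroids (um, assumed 1 um/px).
#' @param cn integer CN labels.
#' @param width,height raster extent in px.
#' @param step rasterization step in px (default 1; larger is coarser and
#'   faster).
#' @return Integer matrix (height x width at resolution `step`) of CN
#'   labels, with class `voronoi_raster`; plot with [plot.voronoi_raster()].
#' @export
voronoi_render <- function(x, y, cn, width, height, step = 1) {
  n <- length(x)
  stopifnot(length(y) == n, length(cn) == n)
  if (n >= 3) {
    colin <- abs((x[2] - x[1]) * (y - y[1]) - (y[2] - y[1]) * (x - x[1])) < 1e-9
    if (all(colin)) {
      warning("collinear centroids; jittering for tessellation")
      local_seed(0L, {
        x <- x + runif(n, -1e-6, 1e-6); y <- y + runif(n, -1e-6, 1e-6)
      })
    }
  }
  gx <- seq(step / 2, width - step / 2, by = step)
  gy <- seq(step / 2, height - step / 2, by = step)
  out <- matrix(0L, length(gy), length(gx))
  pts <- cbind(x, y)
  for (r in seq_along(gy)) {
    d2 <- outer(rep(gy[r]^2, length(gx)) + gx^2, x^2 + y^2, "+") -
      2 * (outer(gx, x) + outer(rep(gy[r], length(gx)), y))
    out[r, ] <- cn[max.col(-d2, ties.method = "first")]
  }
  structure(out, class = "voronoi_raster")
}

#' @rdname voronoi_render
#' @param v a `voronoi_raster`.
#' @param col palette (one colour per CN).
#' @param ... passed to [graphics::image()].
#' @export
plot.voronoi_raster <- function(x, col = grDevices::hcl.colors(max(x), "Dark 3"),
                                ...) {
  m <- unclass(x)
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = col, axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' @importFrom graphics image
NULL
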