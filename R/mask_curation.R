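#' 3x3 median filter
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood; image
#' borders are handled by edge replication. This is the standard despeckle
#' step applied to every raw channel before intensity quantization.
#'
#' @param channel numeric matrix.
#' @return Filtered matrix of the same shape.
#' @export
median_filter_3x3 <- function(channel) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  .median3x3_cpp(channel)
}

#' Quantize a channel into intensity levels by 1-D k-means
#'
#' Pixel intensities are clustered into `k` (default 6) groups with 1-D
#' k-means (k-means++ seeding, Lloyd refinement, multiple restarts,
#' deterministic given `seed`). Groups are relabelled `1..k` in ascending
#' centre intensity, so level `k` is the brightest. When the channel has
#' fewer distinct intensities than `k`, each distinct value becomes its own
#' level (with a warning); a constant channel yields a single level.
#'
#' For large images the restarts are seeded from a deterministic subsample
#' (1e5 pixels) and the best initialisation is polished on the full data,
#' which leaves results deterministic while keeping curation fast.
#'
#' @param channel numeric matrix (typically median-filtered).
#' @param k number of intensity levels; default 6.
#' @param seed integer RNG seed.
#' @param n_restart number of k-means++ restarts; default 10.
#' @return A `level_raster`: list with `levels` (integer matrix, values
#'   `1..k_eff`), `centres` (ascending) and `k` (effective group count).
#' @export
quantize_levels <- function(channel, k = 6L, seed = 0L, n_restart = 10L) {
  stopifnot(k >= 2)
  x <- as.numeric(channel)
  ux <- unique(x)
  if (length(ux) <= k) {
    if (length(ux) < k)
      warning("channel has ", length(ux), " distinct intensities < k = ", k,
              "; using one level per distinct value")
    centres <- sort(ux)
    lev <- matrix(match(x, centres), nrow(channel), ncol(channel))
    return(structure(list(levels = lev, centres = centres, k = length(centres)),
                     class = "level_raster"))
  }
  fit <- local_seed(seed, {
    xs <- if (length(x) > 1e5) {
      x[seq.int(1L, length(x), length.out = 1e5)]  # deterministic stride
    } else x
    best <- NULL
    for (r in seq_len(n_restart)) {
      init <- xs[kmeanspp_init(matrix(xs, ncol = 1), k)]
      f <- .kmeans1d_lloyd_cpp(xs, init, 100L, 1e-10)
      if (is.null(best) || f$withinss < best$withinss) best <- f
    }
    if (length(x) > length(xs)) best <- .kmeans1d_lloyd_cpp(x, best$centers, 100L, 1e-10)
    best
  })
  centres <- fit$centers
  lev <- matrix(.assign1d_cpp(x, centres), nrow(channel), ncol(channel))
  structure(list(levels = lev, centres = centres, k = length(centres)),
            class = "level_raster")
}

#' Select foreground from an intensity-level raster
#'
#' Foreground is the union of the `L` brightest intensity groups (antibody
#' signal is bright-positive); the remaining groups are background. With
#' `L >= k` everything is foreground, so foreground masks are nested in
#' `L`.
#'
#' @param levels a `level_raster` from [quantize_levels()].
#' @param L number of brightest groups kept, `1 <= L <= 6`.
#' @param brightest if `FALSE`, count groups from the dimmest instead
#'   (the opposite convention, off by default).
#' @return Logical matrix (TRUE = foreground).
#' @export
select_foreground <- function(levels, L, brightest = TRUE) {
  if (L < 1 || L > 6) stop("L must be in [1, 6]", call. = FALSE)
  k <- levels$k
  if (brightest) levels$levels > (k - L) else levels$levels <= L
}

#' Remove small connected blobs from a binary mask
#'
#' Connected components (8-connectivity by default) with area below
#' `min_area` px^2 are set to background; applied to curated masks to
#' suppress speckle noise. Idempotent.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area kept.
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix.
#' @export
remove_small_blobs <- function(mask, min_area, connectivity = 8L) {
  stopifnot(is.logical(mask))
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- .label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# mean filter over a (2h+1)-square window with edge clipping, via an
# integral image; the divisor is the number of in-bounds pixels.
local_mean <- function(x, half) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, nr + 1, nc + 1)
  S[2:(nr + 1), 2:(nc + 1)] <- cs
  i0 <- pmax(seq_len(nr) - half, 1L); i1 <- pmin(seq_len(nr) + half, nr)
  j0 <- pmax(seq_len(nc) - half, 1L); j1 <- pmin(seq_len(nc) + half, nc)
  sums <- S[i1 + 1, j1 + 1, drop = FALSE] - S[i0, j1 + 1, drop = FALSE] -
    S[i1 + 1, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  counts <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  sums / counts
}

#' Adaptive-threshold refinement of a curated mask
#'
#' Computes a local-mean adaptive binarization of the channel and
#' intersects it with the input mask, so the result is always a subset of
#' the input (a refinement that removes noise). The local mean is taken
#' over a square window of side `2*floor(min(dim)/16) + 1`; a pixel is
#' foreground in the adaptive mask when its value exceeds
#' `(1 - sensitivity) * local_mean` — higher sensitivity admits more
#' foreground.
#'
#' @param channel numeric matrix (same shape as `mask`).
#' @param mask logical matrix from the blob-removal step.
#' @param sensitivity in `[0, 1]`; default 0.4.
#' @param combine `"intersection"` (default) or `"union"`.
#' @return Logical matrix.
#' @export
adaptive_refine <- function(channel, mask, sensitivity = 0.4,
                            combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  stopifnot(all(dim(channel) == dim(mask)))
  half <- max(1L, as.integer(floor(min(dim(channel)) / 16)))
  adap <- channel > (1 - sensitivity) * local_mean(channel, half)
  if (combine == "intersection") mask & adap else mask | adap
}

#' Percentile contrast enhancement
#'
#' Saturates the bottom and top intensity tails: values below the
#' `low_pct` percentile or above the `high_pct` percentile are clipped to
#' those bounds, compressing extreme outliers while leaving interior
#' values (and hence their ranks) untouched. The subsequent level
#' quantization is scale-free, so no rescaling is applied. A constant
#' channel is returned unchanged with a warning.
#'
#' @param channel numeric matrix.
#' @param low_pct,high_pct saturation percentiles, `0 <= low < high <= 100`.
#' @return Numeric matrix.
#' @export
enhance_contrast <- function(channel, low_pct = 1, high_pct = 99) {
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  rng <- range(channel)
  if (rng[1] == rng[2]) {
    warning("constant channel; contrast enhancement is a no-op")
    return(channel)
  }
  p <- quantile(channel, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (p[1] == p[2]) {
    warning("degenerate percentile range; contrast enhancement is a no-op")
    return(channel)
  }
  pmin(pmax(channel, p[1]), p[2])
}

#' Curate a binary foreground mask for one marker channel
#'
#' The six-step curation sequence applied to each lineage marker:
#' optional percentile contrast enhancement, 3x3 median filtering,
#' 1-D k-means quantization into 6 intensity levels, foreground selection
#' of the brightest `foreground_level` groups, removal of blobs smaller
#' than `min_blob_area`, and (for markers flagged `refine`) adaptive
#' local-mean refinement by intersection. Deterministic given `seed`.
#'
#' @param channel numeric matrix (raw counts).
#' @param params one row of a [marker_panel()] (or any list with fields
#'   `foreground_level`, `min_blob_area`, `refine`, `sensitivity`,
#'   `enhance`, `low_pct`, `high_pct`).
#' @param seed RNG seed for the quantization step.
#' @param log if TRUE, attach per-step foreground pixel counts as the
#'   `"steps"` attribute.
#' @return Logical matrix (the curated mask).
#' @export
curate_mask <- function(channel, params, seed = 0L, log = FALSE) {
  ch <- channel
  if (isTRUE(params$enhance))
    ch <- enhance_contrast(ch, params$low_pct, params$high_pct)
  ch <- median_filter_3x3(ch)
  lev <- quantize_levels(ch, 6L, seed = seed)
  if (lev$k == 1)  # constant channel: no contrast, hence no foreground
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  m <- select_foreground(lev, params$foreground_level)
  steps <- c(selected = sum(m))
  m <- remove_small_blobs(m, params$min_blob_area)
  steps <- c(steps, deblobbed = sum(m))
  if (isTRUE(params$refine)) {
    m <- adaptive_refine(ch, m, params$sensitivity %||% 0.4)
    steps <- c(steps, refined = sum(m))
  }
  if (log) attr(m, "steps") <- steps
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Curate masks for every lineage marker of a stack
#'
#' Runs [curate_mask()] for each lineage marker in the panel; per-marker
#' seeds are derived from the master seed and the (image, marker) pair so
#' results do not depend on execution order.
#'
#' @param stack a [channel_stack()].
#' @param panel a [marker_panel()].
#' @param seed master seed.
#' @param markers which markers to curate; default all lineage markers.
#' @return A `mask_set`: named list of logical matrices plus attributes
#'   `image_id` and `dim`.
#' @export
curate_masks <- function(stack, panel, seed = 0L,
                         markers = lineage_markers(panel)) {
  out <- lapply(markers, function(mk) {
    p <- panel[panel$name == mk, , drop = FALSE]
    if (nrow(p) != 1) stop("marker '", mk, "' not in panel", call. = FALSE)
    curate_mask(channel_of(stack, mk), as.list(p),
                seed = derive_seed(seed, stack$image_id, mk, "curate"))
  })
  names(out) <- markers
  structure(out, image_id = stack$image_id,
            shape = dim(stack$pixels)[2:3], class = "mask_set")
}
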