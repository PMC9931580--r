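#' Per-cell majority vectors from curated marker masks
#'
#' For every cell, counts how many of its pixels fall inside each curated
#' lineage-marker mask. Each pixel contributes a binary presence vector
#' over the lineage markers; summing those vectors over the cell's pixels
#' gives the cell's majority vector, whose entries are exact integer counts
#' bounded by the cell's area.
#'
#' @param seg integer matrix of segmentation labels (0 = background).
#' @param masks a `mask_set` (named list of logical matrices) from
#'   [curate_masks()].
#' @return Integer matrix, cells x markers; row `i` is the majority vector
#'   of cell `i` (label `i` in `seg`).
#' @export
majority_vectors <- function(seg, masks) {
  stopifnot(length(masks) >= 1)
  n <- max(seg)
  if (n < 1) stop("segmentation contains no cells", call. = FALSE)
  out <- vapply(masks, function(m) {
    if (!all(dim(m) == dim(seg)))
      stop("mask/segmentation shape mismatch", call. = FALSE)
    lab <- seg[m]
    tabulate(lab[lab > 0L], nbins = n)
  }, integer(n))
  if (is.null(dim(out)))  # n == 1 guard
    out <- matrix(out, nrow = n, dimnames = list(NULL, names(masks)))
  rownames(out) <- seq_len(n)
  out
}

#' Assign lineages from majority vectors
#'
#' A lineage's vote is the maximum majority-vector count over its defining
#' markers (so co-staining pixels are not double-counted); the lineage with
#' the largest vote wins, ties are broken by rank priority (the lineage
#' listed earlier in the hierarchy), and cells whose majority vector is all
#' zero are `"Undefined"`. Undefined cells keep their expression summaries
#' and take part in all spatial analyses as their own category.
#'
#' @param M integer matrix from [majority_vectors()] (cells x markers,
#'   with marker column names).
#' @param hierarchy a [lineage_hierarchy()].
#' @return Character vector of lineage names, length `nrow(M)`.
#' @export
assign_lineage <- function(M, hierarchy) {
  if (is.null(colnames(M))) stop("M needs marker column names", call. = FALSE)
  bad <- setdiff(unlist(hierarchy), colnames(M))
  if (length(bad))
    stop("hierarchy markers missing from majority vectors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(M)
  best <- rep.int(0L, n)
  lin <- rep.int("Undefined", n)
  for (i in seq_along(hierarchy)) {
    sc <- M[, hierarchy[[i]], drop = FALSE]
    sc <- if (ncol(sc) > 1) do.call(pmax, as.data.frame(sc)) else sc[, 1]
    better <- sc > best  # strict: earlier (higher-priority) lineage keeps ties
    lin[better] <- names(hierarchy)[i]
    best <- pmax(best, sc)
  }
  lin[best == 0L] <- "Undefined"
  lin
}

#' Subphenotype flags from marker positivity
#'
#' A cell is positive for a marker when its majority-vector count for that
#' marker covers at least `frac` of the cell's area (default 0.25, robust
#' to mask speckle while catching partial membrane staining). Flags follow
#' the brain-TME conventions: among macrophage-lineage cells, P2Y12+ marks
#' tissue-resident microglia and P2Y12- marks monocyte-derived macrophages
#' (MDM); CD163 distinguishes M2-like (positive) from M1-like (negative);
#' an MPO+ flag is recorded for the neutrophil-like subset. Rules only
#' apply to cells of the stated lineages.
#'
#' @param lineage character vector of assigned lineages.
#' @param M majority-vector matrix (cells x markers, named columns) — may
#'   include functional markers counted against curated functional masks.
#' @param area integer vector of cell areas (px).
#' @param rules list of rules; each rule is a list with `lineages`
#'   (character, which cells it applies to), `marker`, `pos_flag`,
#'   `neg_flag` (either may be NA). Defaults implement the
#'   microglia/MDM/M1/M2/MPO scheme.
#' @param frac positivity fraction of cell area; default 0.25.
#' @return Character vector of semicolon-joined flags per cell.
#' @export
subphenotype <- function(lineage, M, area, rules = default_subphenotype_rules(),
                         frac = 0.25) {
  n <- length(lineage)
  stopifnot(nrow(M) == n, length(area) == n)
  flags <- vector("list", n)
  for (r in rules) {
    if (!r$marker %in% colnames(M))
      stop("subphenotype rule references unknown marker '", r$marker, "'",
           call. = FALSE)
    applies <- lineage %in% r$lineages
    pos <- M[, r$marker] >= frac * area
    hit_pos <- applies & pos
    hit_neg <- applies & !pos
    if (!is.na(r$pos_flag))
      flags[hit_pos] <- lapply(flags[hit_pos], c, r$pos_flag)
    if (!is.na(r$neg_flag))
      flags[hit_neg] <- lapply(flags[hit_neg], c, r$neg_flag)
  }
  vapply(flags, function(f) paste(unique(unlist(f)), collapse = ";"), character(1))
}

#' @rdname subphenotype
#' @param macrophage_lineages lineage names treated as macrophage/monocyte
#'   for the default rules.
#' @export
default_subphenotype_rules <- function(macrophage_lineages = c("Macrophage")) {
  list(
    list(lineages = macrophage_lineages, marker = "P2Y12",
         pos_flag = "microglia", neg_flag = "MDM"),
    list(lineages = macrophage_lineages, marker = "CD163",
         pos_flag = "M2-like", neg_flag = "M1-like"),
    list(lineages = macrophage_lineages, marker = "MPO",
         pos_flag = "MPO_pos", neg_flag = NA_character_)
  )
}

#' @rdname subphenotype
#' @param sub_flags semicolon-joined flag strings (the `sub_flags` column).
#' @param flag flag name to query.
#' @return [has_flag()] returns a logical vector.
#' @export
has_flag <- function(sub_flags, flag) {
  vapply(strsplit(sub_flags, ";", fixed = TRUE), function(f) flag %in% f,
         logical(1))
}

#' Summarize per-cell marker expression
#'
#' Mean raw pixel value of every channel over each cell's pixels; no
#' transformation is applied (all downstream statistics run on raw
#' measurements). Cells with zero pixels are excluded with a warning.
#'
#' @param seg integer label matrix.
#' @param stack a [channel_stack()].
#' @return Numeric matrix, cells x channels (`expr_<marker>` columns).
#' @export
summarize_expression <- function(seg, stack) {
  stopifnot(all(dim(seg) == dim(stack$pixels)[2:3]))
  n <- max(seg)
  areas <- tabulate(seg[seg > 0L], nbins = n)
  if (any(areas == 0))
    warning("labels with zero pixels excluded: ",
            paste(which(areas == 0), collapse = ", "))
  idx <- seg > 0L
  lab <- seg[idx]
  out <- vapply(seq_along(stack$channels), function(ci) {
    v <- stack$pixels[ci, , ][idx]
    sums <- rep.int(0, n)
    s <- rowsum(v, lab)
    sums[as.integer(rownames(s))] <- s[, 1]
    ifelse(areas > 0, sums / areas, NA_real_)
  }, numeric(n))
  if (is.null(dim(out))) out <- matrix(out, nrow = n)
  colnames(out) <- paste0("expr_", stack$channels)
  out
}

#' Display normalization (95th percentile) and cluster-mean z-scores
#'
#' For heatmap display only (never feeds statistics): values are divided by
#' their `pct`-th percentile and clipped to `[0, 1]`.
#'
#' @param values numeric vector.
#' @param pct percentile used as the normalization constant; default 95.
#' @return Normalized vector in `[0, 1]`.
#' @export
normalize_for_display <- function(values, pct = 95) {
  stopifnot(length(values) > 0)
  p <- quantile(values, pct / 100, names = FALSE, type = 7)
  if (p <= 0) {
    warning("normalization percentile is 0; returning zeros")
    return(rep.int(0, length(values)))
  }
  pmin(pmax(values / p, 0), 1)
}

#' @rdname normalize_for_display
#' @param means matrix of cluster means (clusters x markers).
#' @return [zscore_cluster_means()] returns the matrix z-scored across
#'   clusters within each marker (columns sum to 0).
#' @export
zscore_cluster_means <- function(means) {
  apply(means, 2, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep.int(0, length(v)) else (v - mean(v)) / s
  })
}

#' Build a cell table from segmentation, masks and a channel stack
#'
#' Convenience wrapper tying the phenotyping stages together: centroids and
#' areas from the label mask (centroid = unweighted mean of member pixel
#' coordinates, 0-based, x = column, y = row, in um via `pixel_size_um`),
#' mean expression from the stack, lineage from the pixel-majority vote,
#' and subphenotype flags.
#'
#' @param seg integer label matrix.
#' @param stack a [channel_stack()].
#' @param masks a `mask_set` over the panel's lineage markers (may include
#'   functional-marker masks for subphenotyping).
#' @param hierarchy a [lineage_hierarchy()].
#' @param rules subphenotype rules; `NULL` disables flagging.
#' @return A [cell_table()].
#' @export
phenotype_cells <- function(seg, stack, masks, hierarchy, rules = NULL) {
  n <- max(seg)
  idx <- which(seg > 0L)
  lab <- seg[idx]
  rows <- (idx - 1L) %% nrow(seg)       # 0-based row = y
  cols <- (idx - 1L) %/% nrow(seg)      # 0-based col = x
  area <- tabulate(lab, nbins = n)
  cx <- rep.int(NA_real_, n); cy <- rep.int(NA_real_, n)
  sx <- rowsum(cols, lab); sy <- rowsum(rows, lab)
  got <- as.integer(rownames(sx))
  cx[got] <- sx[, 1] / area[got]
  cy[got] <- sy[, 1] / area[got]
  M <- majority_vectors(seg, masks)
  lin <- assign_lineage(M, hierarchy)
  expr <- summarize_expression(seg, stack)
  df <- data.frame(cell_id = seq_len(n), image_id = stack$image_id,
                   centroid_x_um = cx * stack$pixel_size_um,
                   centroid_y_um = cy * stack$pixel_size_um,
                   area_px = area, lineage = lin,
                   stringsAsFactors = FALSE)
  df$sub_flags <- if (is.null(rules)) "" else subphenotype(lin, M, area, rules)
  cell_table(cbind(df, as.data.frame(expr)))
}
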