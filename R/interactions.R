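#' Fixed-radius neighbour graph
#'
#' Two cells interact when their centroid distance is at most `radius_um`
#' (default 6 um, i.e. 6 px at 1 um/px). Built with grid bucketing but
#' exactly equivalent to the all-pairs check; the graph is undirected with
#' no self-edges.
#'
#' @param x,y centroid coordinates in um.
#' @param radius_um interaction radius; default 6.
#' @return Object of class `neighbour_graph`: list with `edges` (2-column
#'   integer matrix, `i < j`), `n` and `radius_um`.
#' @export
build_graph <- function(x, y, radius_um = 6) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite coordinates", call. = FALSE)
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (n == 1)
    return(structure(list(edges = matrix(integer(), 0, 2), n = 1L,
                          radius_um = radius_um), class = "neighbour_graph"))
  cw <- radius_um
  bx <- floor(x / cw); by <- floor(y / cw)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  bmap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = bmap)
  r2 <- radius_um^2
  ei <- integer(0); ej <- integer(0)
  for (k in names(buckets)) {
    ids <- buckets[[k]]
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    cbx <- as.numeric(parts[1]); cby <- as.numeric(parts[2])
    for (dx in -1:1) for (dy in -1:1) {
      nk <- paste(cbx + dx, cby + dy)
      if (!exists(nk, envir = bmap, inherits = FALSE)) next
      oth <- get(nk, envir = bmap, inherits = FALSE)
      pair <- expand.grid(i = ids, j = oth)
      keep <- pair$i < pair$j
      if (!any(keep)) next
      pi <- pair$i[keep]; pj <- pair$j[keep]
      d2 <- (x[pi] - x[pj])^2 + (y[pi] - y[pj])^2
      ok <- d2 <= r2
      ei <- c(ei, pi[ok]); ej <- c(ej, pj[ok])
    }
  }
  o <- order(ei, ej)
  structure(list(edges = cbind(i = ei[o], j = ej[o]), n = n,
                 radius_um = radius_um), class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("neighbour_graph: %d cells, %d edges, radius %.1f um\n",
              x$n, nrow(x$edges), x$radius_um))
  invisible(x)
}

# directed neighbour-count matrix over T types: cnt[A,B] = number of
# ordered adjacent pairs with labels (A, B)
directed_counts <- function(edges, lab, ntypes) {
  e1 <- c(edges[, 1], edges[, 2])
  e2 <- c(edges[, 2], edges[, 1])
  matrix(tabulate((lab[e1] - 1L) * ntypes + lab[e2], nbins = ntypes * ntypes),
         ntypes, ntypes, byrow = TRUE)
}

#' Pairwise interaction / avoidance permutation tests
#'
#' For every ordered type pair (A, B) of one image, the observed statistic
#' is the mean number of B-neighbours per A-cell in the fixed-radius
#' graph. The null is built by shuffling the phenotype labels over all
#' cells of the image (positions and graph fixed; all cells, including
#' Undefined, are permuted because they occupy space). One-tailed p-values
#' use the add-one estimator `p = (1 + #extreme) / (n_perm + 1)`; a pair
#' is called `interact` when `p_interact < alpha`, `avoid` when
#' `p_avoid < alpha` (alpha = 0.01), otherwise `ns`. Pairs whose A or B
#' type is absent from the image are excluded (recorded as `NA` call).
#' Results are read row-to-column: (A, B) asks whether A-cells have more
#' B-neighbours than expected.
#'
#' @param graph a [build_graph()] result.
#' @param labels character or factor of cell types, length `graph$n`.
#' @param n_perm number of permutations; default 1000.
#' @param alpha significance level; default 0.01.
#' @param seed RNG seed.
#' @param types type alphabet (rows/columns of the result); default the
#'   levels present in `labels`.
#' @return data.frame of class `interaction_result`: one row per ordered
#'   pair with `type_a`, `type_b`, `observed`, `null_mean`, `null_sd`,
#'   `p_interact`, `p_avoid`, `call`, `n_perm`.
#' @export
interaction_test <- function(graph, labels, n_perm = 1000L, alpha = 0.01,
                             seed = 0L, types = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  lab_chr <- as.character(labels)
  if (is.null(types)) types <- sort(unique(lab_chr))
  lab <- match(lab_chr, types)
  if (anyNA(lab)) stop("labels outside the declared type alphabet", call. = FALSE)
  ntypes <- length(types)
  nA <- tabulate(lab, nbins = ntypes)
  edges <- graph$edges
  obs_cnt <- directed_counts(edges, lab, ntypes)
  geq <- matrix(0L, ntypes, ntypes)
  leq <- matrix(0L, ntypes, ntypes)
  s1 <- matrix(0, ntypes, ntypes); s2 <- matrix(0, ntypes, ntypes)
  local_seed(seed, {
    for (p in seq_len(n_perm)) {
      labp <- lab[sample.int(graph$n)]
      cnt <- directed_counts(edges, labp, ntypes)
      geq <- geq + (cnt >= obs_cnt)
      leq <- leq + (cnt <= obs_cnt)
      s1 <- s1 + cnt; s2 <- s2 + cnt^2
    }
  })
  # counts and the per-A-cell mean statistic differ by the constant n_A,
  # which permutation preserves, so count comparisons are exact
  denomA <- matrix(nA, ntypes, ntypes)
  obs <- obs_cnt / denomA
  null_mean <- s1 / n_perm / denomA
  null_sd <- sqrt(pmax(s2 / n_perm - (s1 / n_perm)^2, 0)) / denomA
  p_int <- (1 + geq) / (n_perm + 1)
  p_avd <- (1 + leq) / (n_perm + 1)
  call <- ifelse(p_int < alpha, "interact", ifelse(p_avd < alpha, "avoid", "ns"))
  eligible <- outer(nA > 0, nA > 0, "&")
  call[!eligible] <- NA_character_
  idx <- expand.grid(a = seq_len(ntypes), b = seq_len(ntypes))
  res <- data.frame(type_a = types[idx$a], type_b = types[idx$b],
                    observed = obs[cbind(idx$a, idx$b)],
                    null_mean = null_mean[cbind(idx$a, idx$b)],
                    null_sd = null_sd[cbind(idx$a, idx$b)],
                    p_interact = p_int[cbind(idx$a, idx$b)],
                    p_avoid = p_avd[cbind(idx$a, idx$b)],
                    call = call[cbind(idx$a, idx$b)],
                    n_perm = n_perm, stringsAsFactors = FALSE)
  res[!eligible[cbind(idx$a, idx$b)],
      c("observed", "null_mean", "null_sd", "p_interact", "p_avoid")] <- NA
  class(res) <- c("interaction_result", "data.frame")
  res
}

#' Cohort interaction-avoidance heatmap
#'
#' For every ordered type pair, the score is the fraction of eligible
#' images called `interact` minus the fraction called `avoid`, in
#' `[-1, 1]`, read row-to-column. Images where a pair was excluded do not
#' enter that pair's denominator.
#'
#' @param results list of [interaction_test()] results (one per image).
#' @return Square numeric matrix (types x types); entries are `NaN` when a
#'   pair was eligible in no image.
#' @export
cohort_heatmap <- function(results) {
  all <- do.call(rbind, lapply(results, as.data.frame))
  types <- sort(unique(c(all$type_a, all$type_b)))
  score <- matrix(NaN, length(types), length(types),
                  dimnames = list(types, types))
  for (a in types) for (b in types) {
    calls <- all$call[all$type_a == a & all$type_b == b]
    calls <- calls[!is.na(calls)]
    if (length(calls))
      score[a, b] <- mean(calls == "interact") - mean(calls == "avoid")
  }
  score
}

#' Conditional marker contrast between interacting and avoiding cells
#'
#' Splits the focal type A cells of an image into those with at least one
#' type-B neighbour in the fixed-radius graph ("interacting") and those
#' with none ("avoiding"), and evaluates a per-cell statistic in both
#' groups: a marker's mean expression, or the Ki67:CC3 ratio (proliferation
#' vs apoptosis) guarded by a pseudocount equal to the smallest positive
#' CC3 mean observed in the image (fallback 1e-3). Images lacking either
#' category are flagged excluded.
#'
#' @param cells a [cell_table()] for one image (with `expr_` columns).
#' @param graph the image's [build_graph()] result (same row order).
#' @param focal,partner lineage names A and B.
#' @param statistic `"marker"` or `"ki67_cc3"`.
#' @param marker marker name when `statistic = "marker"`.
#' @param ki67,cc3 channel names for the ratio statistic.
#' @return List with `interacting`, `avoiding` (numeric vectors),
#'   `excluded` (logical) and `test` (a [compare_groups()] result or NULL
#'   when excluded).
#' @export
conditional_contrast <- function(cells, graph, focal, partner,
                                 statistic = c("marker", "ki67_cc3"),
                                 marker = NULL, ki67 = "Ki67", cc3 = "CC3") {
  statistic <- match.arg(statistic)
  stopifnot(nrow(cells) == graph$n)
  lin <- cells$lineage
  isA <- lin == focal
  isB <- lin == partner
  if (!any(isA) || !any(isB))
    return(list(interacting = numeric(0), avoiding = numeric(0),
                excluded = TRUE, test = NULL))
  hasB <- rep.int(FALSE, graph$n)
  e <- graph$edges
  hasB[e[isB[e[, 2]], 1]] <- TRUE
  hasB[e[isB[e[, 1]], 2]] <- TRUE
  val <- if (statistic == "marker") {
    col <- paste0("expr_", marker)
    if (!col %in% names(cells)) stop("no column ", col, call. = FALSE)
    cells[[col]]
  } else {
    kc <- paste0("expr_", ki67); cc <- paste0("expr_", cc3)
    if (!all(c(kc, cc) %in% names(cells)))
      stop("need ", kc, " and ", cc, " columns", call. = FALSE)
    ccv <- cells[[cc]]
    eps <- if (any(ccv > 0)) min(ccv[ccv > 0]) else 1e-3
    cells[[kc]] / (ccv + eps)
  }
  interacting <- val[isA & hasB]
  avoiding <- val[isA & !hasB]
  excluded <- length(interacting) == 0 || length(avoiding) == 0
  test <- if (!excluded && length(interacting) >= 2 && length(avoiding) >= 2) {
    compare_groups(c(interacting, avoiding),
                   rep(c("interacting", "avoiding"),
                       c(length(interacting), length(avoiding))))
  } else NULL
  list(interacting = interacting, avoiding = avoiding,
       excluded = excluded, test = test)
}

#' Density category of a flagged cell population
#'
#' Images are categorized by the density of a flagged population (e.g.
#' MPO+ M1-like MDMs): `none` for zero cells, `low` for up to 5 cells per
#' mm^2, `high` for 6 or more per mm^2. For log-scale display a
#' `display_count` is reported in which zero-cell images take the value 1.
#'
#' @param n_cells number of flagged cells in the image.
#' @param area_mm2 image area in mm^2 (> 0).
#' @return List with `category` (factor none/low/high), `density`
#'   (cells per mm^2) and `display_count`.
#' @export
density_category <- function(n_cells, area_mm2) {
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("image area must be positive", call. = FALSE)
  dens <- n_cells / area_mm2
  cat <- if (n_cells == 0) "none" else if (dens < 6) "low" else "high"
  list(category = factor(cat, levels = c("none", "low", "high")),
       density = dens,
       display_count = if (n_cells == 0) 1 else n_cells)
}
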