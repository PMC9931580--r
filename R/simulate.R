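#' Synthetic tissue configuration
#'
#' Describes the marked point process a synthetic core is drawn from. The
#' defaults emulate a 1 mm^2 IMC core at 1 um/pixel: a 1000 x 1000 px
#' image with 2000 cells rendered as non-overlapping discs of radius 4 px.
#' Cell types are sampled from `proportions`; optional `interactions`
#' plant pairwise attraction (Thomas-process offspring around shared
#' parents) or avoidance (hard-core thinning of one type around the
#' other); optional `regions` plant rectangular neighbourhood zones with
#' their own type compositions (ground truth for CN discovery). Marker
#' channels are rendered as integer counts: lognormal signal (meanlog 3,
#' sdlog 0.4 by default, i.e. median ~20 counts) inside positive cells
#' over an exponential background (mean 0.3), mimicking the skewed count
#' statistics of IMC.
#'
#' @param width,height image size in px (1 um/px).
#' @param n_cells target cell count (realized count can be slightly lower
#'   at high packing density or under hard-core thinning).
#' @param proportions named vector of cell-type proportions (sums to 1).
#' @param cell_radius_px disc radius; default 4.
#' @param interactions list of
#'   `list(pair = c(A, B), mode = "attraction", scale_um = 4)` or
#'   `list(pair = c(A, B), mode = "avoidance", hardcore_um = 8)`.
#' @param regions list of `list(x0, x1, y0, y1, props)` with px bounds and
#'   a named composition; cells falling in a region draw their type from
#'   its composition (later regions override earlier ones).
#' @param signal_meanlog,signal_sdlog lognormal signal parameters.
#' @param background_mean exponential background mean (counts).
#' @param functional list of functional-marker specs:
#'   `list(marker, meanlog, sdlog, modifier = NULL)` where the optional
#'   modifier `list(focal, partner, radius_um, factor)` rescales the
#'   lognormal mean (by `factor`) for focal-type cells with at least one
#'   partner-type neighbour within the radius.
#' @param survival list(base_rate, beta, horizon_days) for cohort-level
#'   survival generation; `beta` is the log hazard ratio per +1 SD of the
#'   planted feature.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(width = 1000L, height = 1000L, n_cells = 2000L,
                       proportions = c(Tumour = 0.4, Macrophage = 0.2,
                                       Astrocyte = 0.15, Endothelial = 0.1,
                                       Tcell = 0.05, Bcell = 0.04,
                                       Neutrophil = 0.03, Undefined = 0.03),
                       cell_radius_px = 4L,
                       interactions = list(),
                       regions = list(),
                       signal_meanlog = 3, signal_sdlog = 0.4,
                       background_mean = 0.3,
                       functional = list(),
                       survival = list(base_rate = 1 / 400, beta = log(2),
                                       horizon_days = 2000)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0),
            width > 0, height > 0, n_cells > 0)
  for (it in interactions)
    stopifnot(length(it$pair) == 2, it$mode %in% c("attraction", "avoidance"))
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells), proportions = proportions,
                 cell_radius_px = as.integer(cell_radius_px),
                 interactions = interactions, regions = regions,
                 signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
                 background_mean = background_mean, functional = functional,
                 survival = survival),
            class = "sim_config")
}

#' Marker panel and hierarchy matching a simulation config
#'
#' One lineage marker per cell type (named `M_<type>`); the `Undefined`
#' type, when present, gets no marker (its cells stain nothing, like
#' cells outside the antibody panel). The hierarchy lists types in the
#' order of `proportions`.
#'
#' @param config a [sim_config()].
#' @return List with `panel` ([marker_panel()]) and `hierarchy`
#'   ([lineage_hierarchy()]).
#' @export
sim_panel <- function(config) {
  types <- setdiff(names(config$proportions), "Undefined")
  panel <- marker_panel(data.frame(name = paste0("M_", types),
                                   role = "lineage",
                                   foreground_level = 5L, min_blob_area = 5L,
                                   stringsAsFactors = FALSE))
  hier <- lineage_hierarchy(setNames(as.list(paste0("M_", types)), types),
                            panel)
  list(panel = panel, hierarchy = hier)
}

# uniform positions in the image, as a 2-column matrix
runif_xy <- function(n, config) {
  cbind(runif(n, 0, config$width), runif(n, 0, config$height))
}

#' Draw synthetic cell positions and types (no rasters)
#'
#' The point-process stage of [generate_image()], exposed on its own
#' because many analyses (interaction calibration, CN recovery, contrast
#' and survival simulations) only need cell tables. Deterministic given
#' `seed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param image_id id recorded in the table.
#' @return A [cell_table()] with truth `lineage` (the planted type),
#'   optional `region` column, and `expr_` columns for any configured
#'   functional markers.
#' @export
generate_cells <- function(config, seed = 0L, image_id = "sim") {
  local_seed(seed, {
    types <- names(config$proportions)
    special <- unique(unlist(lapply(config$interactions, `[[`, "pair")))
    counts <- as.vector(stats::rmultinom(1, config$n_cells, config$proportions))
    names(counts) <- types
    xy <- matrix(numeric(0), 0, 2)
    lab <- character(0)
    for (tp in types) {
      if (tp %in% special) next
      p <- runif_xy(counts[tp], config)
      xy <- rbind(xy, p); lab <- c(lab, rep.int(tp, counts[tp]))
    }
    for (it in config$interactions) {
      A <- it$pair[1]; B <- it$pair[2]
      pa <- runif_xy(counts[A], config)
      if (it$mode == "attraction") {
        parents <- sample.int(max(nrow(pa), 1L), counts[B], replace = TRUE)
        pb <- pa[parents, , drop = FALSE] +
          matrix(rnorm(2 * counts[B], sd = it$scale_um %||% 4), ncol = 2)
        pb[, 1] <- pmin(pmax(pb[, 1], 0), config$width)
        pb[, 2] <- pmin(pmax(pb[, 2], 0), config$height)
      } else {
        hc <- it$hardcore_um %||% 8
        pb <- runif_xy(counts[B], config)
        if (nrow(pa) && nrow(pb)) {
          d2 <- cross_dist2(pb, pa)
          pb <- pb[apply(d2, 1, min) > hc^2, , drop = FALSE]  # Matern-II thinning
        }
      }
      xy <- rbind(xy, pa, pb)
      lab <- c(lab, rep.int(A, nrow(pa)), rep.int(B, nrow(pb)))
    }
    region <- rep.int(0L, nrow(xy))
    if (length(config$regions)) {
      for (ri in seq_along(config$regions)) {
        r <- config$regions[[ri]]
        inr <- xy[, 1] >= r$x0 & xy[, 1] <= r$x1 &
          xy[, 2] >= r$y0 & xy[, 2] <= r$y1
        region[inr] <- ri
        if (any(inr))
          lab[inr] <- sample(names(r$props), sum(inr), replace = TRUE,
                             prob = r$props)
      }
    }
    df <- data.frame(cell_id = seq_along(lab), image_id = image_id,
                     centroid_x_um = xy[, 1], centroid_y_um = xy[, 2],
                     area_px = NA_real_, lineage = lab, region = region,
                     stringsAsFactors = FALSE)
    for (fm in config$functional) {
      ml <- rep.int(fm$meanlog, nrow(df))
      if (!is.null(fm$modifier)) {
        mo <- fm$modifier
        g <- build_graph(df$centroid_x_um, df$centroid_y_um,
                         mo$radius_um %||% 6)
        isB <- df$lineage == mo$partner
        hasB <- rep.int(FALSE, nrow(df))
        e <- g$edges
        if (nrow(e)) {
          hasB[e[isB[e[, 2]], 1]] <- TRUE
          hasB[e[isB[e[, 1]], 2]] <- TRUE
        }
        mod <- df$lineage == mo$focal & hasB
        ml[mod] <- ml[mod] + log(mo$factor)
      }
      df[[paste0("expr_", fm$marker)]] <-
        rlnorm(nrow(df), meanlog = ml, sdlog = fm$sdlog %||% 0.3)
    }
    df$area_px <- pi * config$cell_radius_px^2  # nominal; rasters refine it
    cell_table(df)
  })
}

# greedy packing: keep cells whose centres are >= min_sep apart, jittering
# conflicting cells up to 20 times before dropping them
pack_cells <- function(xy, min_sep, width, height) {
  n <- nrow(xy)
  keep <- logical(n)
  kept_x <- numeric(0); kept_y <- numeric(0)
  out <- xy
  for (i in seq_len(n)) {
    ok <- FALSE
    cand <- xy[i, ]
    for (try in 0:20) {
      if (!length(kept_x) ||
          min((kept_x - cand[1])^2 + (kept_y - cand[2])^2) >= min_sep^2) {
        ok <- TRUE; break
      }
      cand <- c(min(max(xy[i, 1] + rnorm(1, sd = min_sep), 0), width),
                min(max(xy[i, 2] + rnorm(1, sd = min_sep), 0), height))
    }
    if (ok) {
      keep[i] <- TRUE
      out[i, ] <- cand
      kept_x <- c(kept_x, cand[1]); kept_y <- c(kept_y, cand[2])
    }
  }
  list(xy = out, keep = keep)
}

#' Generate one full synthetic image
#'
#' Draws cells with [generate_cells()], packs them into non-overlapping
#' discs (conflicting cells are jittered, then dropped if packing is
#' infeasible — an error is raised if fewer than half survive), rasterizes
#' the segmentation mask and renders one channel per marker of the
#' matching [sim_panel()]: lognormal signal inside cells positive for the
#' marker plus exponential background everywhere, rounded to integer
#' counts. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param image_id image id.
#' @return List with `stack` ([channel_stack()]), `seg` (integer label
#'   matrix) and `cells` (ground-truth [cell_table()] with realized
#'   centroids and areas).
#' @export
generate_image <- function(config, seed = 0L, image_id = "sim") {
  cells <- generate_cells(config, seed = derive_seed(seed, image_id, "cells"),
                          image_id = image_id)
  r <- config$cell_radius_px
  packed <- local_seed(derive_seed(seed, image_id, "pack"),
                       pack_cells(cbind(cells$centroid_x_um, cells$centroid_y_um),
                                  2 * r + 1, config$width, config$height))
  if (mean(packed$keep) < 0.5)
    stop("infeasible packing: only ", sum(packed$keep), " of ",
         nrow(cells), " cells fit; reduce n_cells or cell_radius_px",
         call. = FALSE)
  cells <- cells[packed$keep, , drop = FALSE]
  cells$centroid_x_um <- packed$xy[packed$keep, 1]
  cells$centroid_y_um <- packed$xy[packed$keep, 2]
  cells$cell_id <- seq_len(nrow(cells))
  h <- config$height; w <- config$width
  seg <- matrix(0L, h, w)
  cx <- round(cells$centroid_x_um); cy <- round(cells$centroid_y_um)
  dd <- expand.grid(dx = -r:r, dy = -r:r)
  dd <- dd[dd$dx^2 + dd$dy^2 <= r^2, ]
  for (i in seq_len(nrow(cells))) {
    px <- cx[i] + dd$dx; py <- cy[i] + dd$dy
    inb <- px >= 0 & px < w & py >= 0 & py < h
    seg[cbind(py[inb] + 1L, px[inb] + 1L)] <- i
  }
  areas <- tabulate(seg[seg > 0L], nbins = nrow(cells))
  cells$area_px <- areas
  # recompute centroids from the raster so truth matches regionprops
  idx <- which(seg > 0L)
  lab <- seg[idx]
  rows0 <- (idx - 1L) %% h; cols0 <- (idx - 1L) %/% h
  sx <- rowsum(cols0, lab); sy <- rowsum(rows0, lab)
  got <- as.integer(rownames(sx))
  cells$centroid_x_um[got] <- sx[, 1] / areas[got]
  cells$centroid_y_um[got] <- sy[, 1] / areas[got]
  sp <- sim_panel(config)
  markers <- sp$panel$name
  arr <- local_seed(derive_seed(seed, image_id, "channels"), {
    a <- array(0, dim = c(length(markers), h, w))
    for (mi in seq_along(markers)) {
      tp <- sub("^M_", "", markers[mi])
      ch <- matrix(round(rexp(h * w, 1 / config$background_mean)), h, w)
      incell <- which(seg > 0L)
      pos <- incell[cells$lineage[seg[incell]] == tp]
      if (length(pos))
        ch[pos] <- ch[pos] + round(rlnorm(length(pos), config$signal_meanlog,
                                          config$signal_sdlog))
      a[mi, , ] <- ch
    }
    a
  })
  stack <- channel_stack(arr, image_id, markers)
  list(stack = stack, seg = seg, cells = cell_table(as.data.frame(cells)))
}

#' Completely random null image (cells only)
#'
#' CSR positions with labels drawn i.i.d. from the configured type
#' proportions, independent of position: the calibration substrate for the
#' interaction permutation test. Interaction and region settings are
#' ignored.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param image_id image id.
#' @return A [cell_table()].
#' @export
null_image <- function(config, seed = 0L, image_id = "null") {
  local_seed(seed, {
    xy <- runif_xy(config$n_cells, config)
    lab <- sample(names(config$proportions), config$n_cells, replace = TRUE,
                  prob = config$proportions)
    cell_table(data.frame(cell_id = seq_len(config$n_cells),
                          image_id = image_id,
                          centroid_x_um = xy[, 1], centroid_y_um = xy[, 2],
                          area_px = pi * config$cell_radius_px^2,
                          lineage = lab, stringsAsFactors = FALSE))
  })
}

#' Survival times under a planted log-linear hazard
#'
#' Exponential survival with per-patient rate
#' `base_rate * exp(beta * z)` where `z` is the standardized planted
#' feature; administrative censoring at the horizon.
#'
#' @param feature numeric planted feature per patient (e.g. CN prevalence).
#' @param base_rate baseline hazard (events per day).
#' @param beta log hazard ratio per +1 SD of the feature.
#' @param horizon_days administrative censoring time.
#' @param seed RNG seed.
#' @return data.frame with `overall_survival_days` and `event`.
#' @export
simulate_survival <- function(feature, base_rate = 1 / 400, beta = log(2),
                              horizon_days = 2000, seed = 0L) {
  z <- if (sd(feature) > 0) (feature - mean(feature)) / sd(feature)
       else rep.int(0, length(feature))
  local_seed(seed, {
    t <- rexp(length(feature), rate = base_rate * exp(beta * z))
    event <- as.integer(t <= horizon_days)
    data.frame(overall_survival_days = pmin(t, horizon_days), event = event)
  })
}

#' Generate a synthetic cohort
#'
#' Allocates images to patients (one or two cores each, mirroring
#' duplicate cores), draws each image's cells with [generate_cells()]
#' (or full rasters with [generate_image()] when `rasters = TRUE`),
#' computes a per-patient planted feature (by default the fraction of
#' cells of `feature_type`, averaged over the patient's images) and draws
#' survival from the configured hazard. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param n_images number of images (>= n_patients).
#' @param n_patients number of patients.
#' @param seed master seed.
#' @param feature_fn function(cell_table) -> scalar planted feature;
#'   default the fraction of cells of the first configured type.
#' @param rasters also generate channel stacks and segmentation masks.
#' @return List with `cells` (all images row-bound, with `patient_id`),
#'   `clinical` ([clinical_table()]), `features` (per patient),
#'   `images` (per-image outputs when `rasters = TRUE`).
#' @export
generate_cohort <- function(config, n_images, n_patients, seed = 0L,
                            feature_fn = NULL, rasters = FALSE) {
  stopifnot(n_images >= n_patients)
  if (is.null(feature_fn)) {
    ft <- names(config$proportions)[1]
    feature_fn <- function(cells) mean(cells$lineage == ft)
  }
  pat <- local_seed(derive_seed(seed, "alloc"), {
    base <- seq_len(n_patients)
    extra <- sample(rep_len(base, n_images - n_patients))
    sort(c(base, extra))
  })
  imgs <- vector("list", n_images)
  tabs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("img%03d", i)
    if (rasters) {
      imgs[[i]] <- generate_image(config, seed = derive_seed(seed, id), image_id = id)
      tabs[[i]] <- imgs[[i]]$cells
    } else {
      tabs[[i]] <- generate_cells(config, seed = derive_seed(seed, id), image_id = id)
    }
    tabs[[i]]$patient_id <- sprintf("pat%03d", pat[i])
  }
  cells <- cell_table(do.call(rbind, lapply(tabs, as.data.frame)))
  imgfeat <- vapply(tabs, feature_fn, numeric(1))
  feat <- tapply(imgfeat, sprintf("pat%03d", pat), mean)
  sv <- simulate_survival(as.numeric(feat),
                          base_rate = config$survival$base_rate,
                          beta = config$survival$beta,
                          horizon_days = config$survival$horizon_days,
                          seed = derive_seed(seed, "survival"))
  clin <- clinical_table(data.frame(patient_id = names(feat),
                                    overall_survival_days = sv$overall_survival_days,
                                    event = sv$event,
                                    stringsAsFactors = FALSE))
  list(cells = cells, clinical = clin,
       features = setNames(as.numeric(feat), names(feat)),
       images = if (rasters) imgs else NULL)
}
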