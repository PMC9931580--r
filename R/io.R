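#' Multichannel image stack
#'
#' One acquisition (e.g. a 1 mm^2 IMC core at 1 um/pixel): a channel x
#' height x width array of non-negative counts, one channel per panel
#' marker.
#'
#' @param pixels numeric array `(channel, height, width)`, all values >= 0.
#' @param image_id character scalar.
#' @param channels character vector of marker names, length `dim(pixels)[1]`.
#' @param pixel_size_um physical pixel size; default 1.
#' @param meta optional named list (disease group, patient id, ...).
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(pixels, image_id, channels,
                          pixel_size_um = 1, meta = list()) {
  stopifnot(length(dim(pixels)) == 3)
  if (length(channels) != dim(pixels)[1])
    stop("channels length must match first array dimension", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (any(dim(pixels)[2:3] < 1)) stop("empty image", call. = FALSE)
  structure(list(pixels = pixels, image_id = image_id,
                 channels = channels, pixel_size_um = pixel_size_um,
                 meta = meta),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("channel_stack '%s': %d channels, %d x %d px (%.1f um/px)\n",
              x$image_id, d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}

# channel matrix (height x width) by marker name
channel_of <- function(stack, marker) {
  i <- match(marker, stack$channels)
  if (is.na(i)) stop("no channel named '", marker, "'", call. = FALSE)
  stack$pixels[i, , ]
}

uint32_to_unit <- function(x) x / (2^32 - 1)

check_integral <- function(x, what) {
  if (any(x < 0) || any(x != round(x)) || any(x >= 2^31))
    stop(what, " must hold non-negative integer counts below 2^31", call. = FALSE)
}

#' Read / write a channel stack as multi-page TIFF
#'
#' One page per channel; counts are stored as 32-bit integers, so the
#' round-trip is bit-exact. Channel names are written to a plain-text
#' sidecar `<path>.channels.txt` (one name per line); on reading, pages are
#' matched to the panel by those names. Without a sidecar the pages are
#' taken in panel order, which must be confirmed with `match_by_order =
#' TRUE` (silent order mismatches are the dominant failure mode for IMC
#' data, so the confirmation is deliberate).
#'
#' @param path TIFF path.
#' @param panel a [marker_panel()].
#' @param image_id id to assign; default the file name without extension.
#' @param match_by_order set `TRUE` to accept page order as channel order
#'   when no sidecar is present.
#' @return A `channel_stack` with channels ordered as the panel.
#' @export
read_channel_stack <- function(path, panel, image_id = NULL,
                               match_by_order = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".channels.txt")
  if (file.exists(sidecar)) {
    nm <- readLines(sidecar)
    if (length(nm) != length(pages))
      stop("sidecar lists ", length(nm), " channels but TIFF has ",
           length(pages), " pages", call. = FALSE)
    missing <- setdiff(panel$name, nm)
    if (length(missing))
      stop("channels missing from image: ", paste(missing, collapse = ", "),
           call. = FALSE)
    pages <- pages[match(panel$name, nm)]
  } else {
    if (length(pages) != nrow(panel))
      stop("TIFF has ", length(pages), " pages but panel has ",
           nrow(panel), " markers (",
           paste(panel$name, collapse = ", "), ")", call. = FALSE)
    if (!isTRUE(match_by_order))
      stop("no channel-name sidecar found; pass match_by_order = TRUE to ",
           "accept page order as panel order", call. = FALSE)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(nrow(panel), h, w))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  channel_stack(arr, image_id, panel$name)
}

#' @rdname read_channel_stack
#' @param stack a `channel_stack` of integer counts.
#' @export
write_channel_stack <- function(stack, path) {
  check_integral(stack$pixels, "channel stack")
  pages <- lapply(seq_along(stack$channels), function(i)
    uint32_to_unit(stack$pixels[i, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(stack$channels, paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read / write a segmentation label mask
#'
#' Single-page integer TIFF; 0 is background, `k > 0` marks the pixels of
#' cell `k`. Stored as 32-bit integers (bit-exact round-trip).
#'
#' @param path TIFF path.
#' @return [read_segmentation()] returns an integer matrix.
#' @export
read_segmentation <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_segmentation
#' @param labels integer matrix of cell labels.
#' @export
write_segmentation <- function(labels, path) {
  check_integral(labels, "segmentation mask")
  tiff::writeTIFF(uint32_to_unit(labels), path, bits.per.sample = 32L)
  invisible(path)
}

cell_table_required <- c("cell_id", "image_id", "centroid_x_um",
                         "centroid_y_um", "area_px", "lineage")

#' Cell table
#'
#' The pipeline's central record: one row per segmented cell with centroid
#' (um), pixel area, per-channel mean expression (columns prefixed
#' `expr_`), assigned lineage (`"Undefined"` when no lineage marker
#' covers the cell), subphenotype flags (`sub_flags`, semicolon-separated),
#' and optional neighbourhood (`cn_label`) and phenotype-cluster
#' (`cluster_label`) assignments. Arbitrary extra columns are preserved.
#'
#' @param df data.frame with at least the mandatory columns
#'   (`cell_id`, `image_id`, `centroid_x_um`, `centroid_y_um`, `area_px`,
#'   `lineage`).
#' @return Object of class `cell_table` (a data.frame).
#' @export
cell_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(cell_table_required, names(df))
  if (length(missing))
    stop("cell table lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  expr <- grep("^expr_", names(df), value = TRUE)
  if (length(expr) && any(as.matrix(df[expr]) < 0, na.rm = TRUE))
    stop("mean expression must be non-negative", call. = FALSE)
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @rdname cell_table
#' @param path CSV path.
#' @export
read_cell_table <- function(path) {
  cell_table(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname cell_table
#' @param cells a `cell_table`.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Clinical records
#'
#' One row per patient: `patient_id`, `overall_survival_days` (> 0) and
#' `event` (1 = death observed, 0 = censored at last follow-up); any
#' further columns (e.g. survivor-group or methylation labels) are kept.
#'
#' @param df data.frame of per-patient records.
#' @return Validated data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("patient_id", "overall_survival_days", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$patient_id))
    stop("one record per patient required", call. = FALSE)
  if (any(df$overall_survival_days <= 0))
    stop("survival days must be positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (observed)", call. = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @rdname clinical_table
#' @param path CSV path.
#' @export
read_clinical <- function(path) {
  clinical_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname clinical_table
#' @param clin a `clinical_table`.
#' @export
write_clinical <- function(clin, path) {
  write.csv(as.data.frame(clin), path, row.names = FALSE)
  invisible(path)
}

#' Join cells with clinical records into a cohort
#'
#' Checks that every image's `patient_id` has a clinical record and
#' returns a cohort view that downstream survival analyses use. All
#' per-image features destined for survival analysis must first be
#' averaged over each patient's images (duplicate cores), so that each
#' patient contributes exactly one value; [average_by_patient()] does
#' this.
#'
#' @param cells a [cell_table()] carrying a `patient_id` column.
#' @param clin a [clinical_table()].
#' @return Object of class `imc_cohort`: list with `cells`, `clinical`
#'   and an `images` data.frame mapping `image_id` to `patient_id`.
#' @export
attach_clinical <- function(cells, clin) {
  if (is.null(cells$patient_id))
    stop("cell table needs a 'patient_id' column", call. = FALSE)
  images <- unique(as.data.frame(cells)[c("image_id", "patient_id")])
  bad <- setdiff(images$patient_id, clin$patient_id)
  if (length(bad))
    stop("patients missing from clinical table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(cells = cells, clinical = clin, images = images),
            class = "imc_cohort")
}

#' Average per-image features over each patient's images
#'
#' Patients contributing several cores must enter survival analyses once;
#' every numeric feature is replaced by its arithmetic mean over that
#' patient's images.
#'
#' @param features data.frame with an `image_id` column plus numeric
#'   feature columns.
#' @param cohort an `imc_cohort` (supplies the image-to-patient map).
#' @return data.frame with one row per patient.
#' @export
average_by_patient <- function(features, cohort) {
  map <- cohort$images
  idx <- match(features$image_id, map$image_id)
  if (anyNA(idx))
    stop("unknown image ids: ",
         paste(features$image_id[is.na(idx)], collapse = ", "), call. = FALSE)
  pid <- map$patient_id[idx]
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  out <- aggregate(features[num], by = list(patient_id = pid), FUN = mean)
  out[order(out$patient_id), , drop = FALSE]
}

#' Validate an on-disk input bundle
#'
#' Checks that every image TIFF in `dir` matches the panel (page count /
#' channel names) and that its segmentation mask, when present as
#' `<image>_seg.tiff`, has the same height and width.
#'
#' @param dir directory containing `*_img.tiff` stacks (with channel
#'   sidecars) and optional `*_seg.tiff` masks.
#' @param panel a [marker_panel()].
#' @return Invisibly, a data.frame of per-image check results; problems
#'   raise errors.
#' @export
validate_bundle <- function(dir, panel) {
  imgs <- list.files(dir, pattern = "_img\\.tiff?$", full.names = TRUE)
  if (!length(imgs)) stop("no *_img.tiff images under ", dir, call. = FALSE)
  res <- lapply(imgs, function(p) {
    st <- read_channel_stack(p, panel)
    segp <- sub("_img\\.tiff?$", "_seg.tiff", p)
    if (file.exists(segp)) {
      seg <- read_segmentation(segp)
      if (!all(dim(seg) == dim(st$pixels)[2:3]))
        stop("segmentation/image shape mismatch for ", p, call. = FALSE)
    }
    data.frame(image_id = st$image_id, n_channels = length(st$channels),
               height = dim(st$pixels)[2], width = dim(st$pixels)[3])
  })
  invisible(do.call(rbind, res))
}

#' @importFrom stats aggregate
NULL
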