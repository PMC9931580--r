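#' Marker panel definition
#'
#' A marker panel lists the antibody channels of a multiplexed image and the
#' per-marker mask-curation parameters: the role of the marker (`"lineage"`
#' markers drive cell-type assignment, `"functional"` markers are summarised
#' but never vote), the number of intensity levels kept as foreground
#' (`foreground_level`, 1--6, counting from the brightest group), the minimum
#' connected-blob area in px^2, whether the adaptive-threshold refinement
#' step is applied (`refine`), and optional contrast enhancement with
#' saturation percentiles (`enhance`, `low_pct`, `high_pct`).
#'
#' @param markers a `data.frame` with columns `name` and `role`
#'   (`"lineage"`/`"functional"`) and optionally `foreground_level`,
#'   `min_blob_area`, `refine`, `enhance`, `low_pct`, `high_pct`; missing
#'   columns are filled with defaults (level 5 — the exponential-like
#'   background of a stained channel concentrates in the dimmest of the
#'   six groups while the lognormal signal spreads over the rest — area
#'   4 px^2, no refine, no enhancement).
#' @return An object of class `marker_panel` (a validated data.frame).
#' @export
marker_panel <- function(markers) {
  m <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!all(c("name", "role") %in% names(m)))
    stop("panel needs 'name' and 'role' columns", call. = FALSE)
  defaults <- list(foreground_level = 5L, min_blob_area = 4L,
                   refine = FALSE, sensitivity = 0.4,
                   enhance = FALSE, low_pct = 1, high_pct = 99)
  for (nm in names(defaults)) if (is.null(m[[nm]])) m[[nm]] <- defaults[[nm]]
  m$foreground_level <- as.integer(m$foreground_level)
  m$min_blob_area <- as.integer(m$min_blob_area)
  if (anyDuplicated(m$name))
    stop("duplicate marker names: ",
         paste(unique(m$name[duplicated(m$name)]), collapse = ", "), call. = FALSE)
  if (!all(m$role %in% c("lineage", "functional")))
    stop("marker role must be 'lineage' or 'functional'", call. = FALSE)
  if (any(m$foreground_level < 1L | m$foreground_level > 6L))
    stop("foreground_level must be in [1, 6]", call. = FALSE)
  if (!any(m$role == "lineage"))
    stop("panel must contain at least one lineage marker", call. = FALSE)
  if (any(m$low_pct < 0 | m$high_pct > 100 | m$low_pct >= m$high_pct))
    stop("need 0 <= low_pct < high_pct <= 100", call. = FALSE)
  class(m) <- c("marker_panel", "data.frame")
  m
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", nrow(x), "markers (",
      sum(x$role == "lineage"), "lineage /",
      sum(x$role == "functional"), "functional )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

lineage_markers <- function(panel) panel$name[panel$role == "lineage"]

#' Read / write a marker panel as YAML
#'
#' The YAML file holds a top-level `markers` sequence, each entry a mapping
#' with the fields of [marker_panel()].
#'
#' @param path file path.
#' @return [read_panel()] returns a `marker_panel`; [write_panel()] returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop("panel YAML must have a 'markers' list", call. = FALSE)
  cols <- unique(unlist(lapply(y$markers, names)))
  rows <- lapply(y$markers, function(e) {
    e[setdiff(cols, names(e))] <- NA   # entries may omit optional fields
    as.data.frame(e[cols], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (nm in names(df))                 # NA -> per-column default
    if (anyNA(df[[nm]])) df[[nm]][is.na(df[[nm]])] <-
      switch(nm, foreground_level = 5L, min_blob_area = 4L, refine = FALSE,
             sensitivity = 0.4, enhance = FALSE, low_pct = 1, high_pct = 99,
             stop("missing value for mandatory field '", nm, "'", call. = FALSE))
  marker_panel(df)
}

#' @rdname read_panel
#' @param panel a `marker_panel`.
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(list(markers = lapply(seq_len(nrow(panel)), function(i)
    as.list(panel[i, , drop = FALSE]))), path)
  invisible(path)
}

#' Lineage hierarchy (rank-priority order)
#'
#' An ordered list of lineages, each defined by a set of lineage markers.
#' The order encodes rank priority: when a cell's pixel-majority vote is
#' tied between lineages, the lineage listed first wins. A lineage's score
#' is the maximum of its defining markers' votes, so multi-marker
#' definitions do not double-count co-staining pixels.
#'
#' @param lineages named list: `list(Tumour = c("SOX2"), Endothelial = "CD31", ...)`
#'   in decreasing priority order.
#' @param panel optional `marker_panel`; if given, defining markers are
#'   checked against the panel's lineage markers.
#' @return Object of class `lineage_hierarchy`.
#' @export
lineage_hierarchy <- function(lineages, panel = NULL) {
  if (is.null(names(lineages)) || any(names(lineages) == ""))
    stop("lineages must be a named list", call. = FALSE)
  if (anyDuplicated(names(lineages)))
    stop("duplicate lineage names", call. = FALSE)
  lineages <- lapply(lineages, as.character)
  if (!is.null(panel)) {
    lm <- lineage_markers(panel)
    bad <- setdiff(unlist(lineages), lm)
    if (length(bad))
      stop("defining markers not lineage markers in panel: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(lineages, class = "lineage_hierarchy")
}

#' @export
print.lineage_hierarchy <- function(x, ...) {
  cat("Lineage hierarchy (rank priority order):\n")
  for (i in seq_along(x))
    cat(sprintf("  %2d. %s: %s\n", i, names(x)[i], paste(x[[i]], collapse = ", ")))
  invisible(x)
}

#' @rdname lineage_hierarchy
#' @param path file path to a YAML file with a top-level `lineages` mapping.
#' @export
read_hierarchy <- function(path, panel = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$lineages)) stop("hierarchy YAML must have 'lineages'", call. = FALSE)
  lineage_hierarchy(y$lineages, panel)
}

#' @rdname lineage_hierarchy
#' @param hierarchy a `lineage_hierarchy`.
#' @export
write_hierarchy <- function(hierarchy, path) {
  yaml::write_yaml(list(lineages = lapply(unclass(hierarchy), as.list)), path)
  invisible(path)
}
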