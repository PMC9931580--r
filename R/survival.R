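#' Per-image cell-type frequencies
#'
#' Frequency of each cell type as a percentage of all cells in the image
#' (Undefined included); percentages sum to 100.
#'
#' @param types cell-type labels of one image.
#' @param type_levels optional full type alphabet.
#' @return Named numeric vector of percentages.
#' @export
cell_frequency <- function(types, type_levels = NULL) {
  stopifnot(length(types) > 0)
  tch <- as.character(types)
  if (is.null(type_levels)) type_levels <- sort(unique(tch))
  100 * table(factor(tch, levels = type_levels)) / length(tch)
}

#' Per-image cell-type densities
#'
#' Cells per mm^2 for each type; the area comes from image metadata or the
#' mask extent (e.g. a 1.5 mm circular core has area pi * 0.75^2 mm^2).
#'
#' @param types cell-type labels of one image.
#' @param area_mm2 image area in mm^2 (> 0).
#' @param type_levels optional full type alphabet.
#' @return Named numeric vector of densities (cells per mm^2).
#' @export
cell_density <- function(types, area_mm2, type_levels = NULL) {
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("image area must be positive", call. = FALSE)
  tch <- as.character(types)
  if (is.null(type_levels)) type_levels <- sort(unique(tch))
  table(factor(tch, levels = type_levels)) / area_mm2
}

#' Group comparison with normality-driven test selection
#'
#' Two groups: Shapiro-Wilk on each group at level 0.05 decides between
#' Student's t-test (both normal) and the Mann-Whitney rank test; with
#' large samples (both groups at least `large_n`) the t-test is used
#' regardless, following large-sample practice. Paired comparisons (from
#' patient-matched samples) use the paired variants. More than two
#' groups: one-way ANOVA with Tukey multiple comparisons. The selection
#' rule is a pure function of the data and is recorded in the result.
#'
#' @param values numeric vector.
#' @param group group label per value (2+ groups, 2+ values each).
#' @param paired logical; only valid for two equal-sized groups.
#' @param large_n per-group size at which the t-test is forced; default 30.
#' @return List of class `group_comparison`: `test` (name), `p`
#'   (two-sided), `groups`, plus `tukey` (pairwise table) for ANOVA and
#'   the underlying `fit`.
#' @export
compare_groups <- function(values, group, paired = FALSE, large_n = 30L) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  ns <- table(group)
  if (nlevels(group) < 2 || any(ns < 2))
    stop("need at least two groups with two values each", call. = FALSE)
  if (nlevels(group) > 2) {
    if (paired) stop("paired comparisons need exactly two groups", call. = FALSE)
    fit <- aov(values ~ group)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$group
    return(structure(list(test = "one-way ANOVA", p = p,
                          groups = levels(group), tukey = tk, fit = fit),
                     class = "group_comparison"))
  }
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  if (length(unique(c(g1, g2))) == 1)  # fully tied: no evidence either way
    return(structure(list(test = "Mann-Whitney", p = 1,
                          groups = levels(group), fit = NULL),
                     class = "group_comparison"))
  swp <- function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3 || length(v) < 3) return(0)   # degenerate: not normal
    shapiro.test(v[seq_len(min(length(v), 5000))])$p.value
  }
  parametric <- (min(ns) >= large_n) || (swp(g1) >= 0.05 && swp(g2) >= 0.05)
  if (parametric) {
    fit <- t.test(g1, g2, paired = paired, var.equal = TRUE)
    test <- if (paired) "paired t-test" else "Student's t-test"
  } else {
    fit <- suppressWarnings(wilcox.test(g1, g2, paired = paired, exact = FALSE))
    test <- if (paired) "paired Wilcoxon" else "Mann-Whitney"
  }
  structure(list(test = test, p = fit$p.value, groups = levels(group),
                 fit = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%s)\n", x$test, x$p,
              paste(x$groups, collapse = " vs ")))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the log-rank
#' (Mantel-Cox) test. Callers must supply one value per patient: per-image
#' features are averaged over each patient's cores first (see
#' [average_by_patient()]) so no patient is represented twice.
#'
#' @param time survival times (> 0), one per patient.
#' @param event 1 = event observed, 0 = censored.
#' @param group group factor (2+ levels, each patient in exactly one).
#' @return List of class `survival_result`: `fit` (a
#'   [survival::survfit] object), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(tapply(event, group, sum) == 0))
    warning("a group has no observed events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  structure(list(fit = fit, chisq = unname(sd_$chisq), df = df, p = p,
                 obs = sd_$obs, exp = sd_$exp),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("log-rank (Mantel-Cox): chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric test; margins must be non-empty.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin: test undefined", call. = FALSE)
  fisher.test(tab)$p.value
}
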