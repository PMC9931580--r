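test_that("fixed-radius graph is exact against the all-pairs oracle", {
  g <- build_graph(c(0, 5), c(0, 0), 6)
  expect_equal(nrow(g$edges), 1)
  g2 <- build_graph(c(0, 7), c(0, 0), 6)
  expect_equal(nrow(g2$edges), 0)
  expect_equal(nrow(build_graph(3, 4, 6)$edges), 0)   # single cell
  expect_error(build_graph(c(0, NA), c(0, 1)), "non-finite")
  set.seed(1)
  for (r in 1:5) {
    n <- 200
    x <- runif(n, 0, 120); y <- runif(n, 0, 120)
    g3 <- build_graph(x, y, 6)
    expect_equal(unname(g3$edges), unname(oracle_graph(x, y, 6)))
  }
})

test_that("permutation test excludes absent types and is deterministic", {
  set.seed(2)
  g <- build_graph(runif(60, 0, 40), runif(60, 0, 40), 6)
  lab <- rep("A", 60)
  res <- interaction_test(g, lab, n_perm = 200, seed = 1,
                          types = c("A", "B"))
  expect_true(is.na(res$call[res$type_a == "A" & res$type_b == "B"]))
  expect_true(is.na(res$call[res$type_a == "B" & res$type_b == "B"]))
  lab2 <- sample(c("A", "B"), 60, replace = TRUE)
  r1 <- interaction_test(g, lab2, n_perm = 300, seed = 9)
  r2 <- interaction_test(g, lab2, n_perm = 300, seed = 9)
  expect_identical(r1, r2)
  # p-values in (0, 1]; interact and avoid never both called
  expect_true(all(r1$p_interact > 0 & r1$p_interact <= 1))
  expect_false(any(r1$p_interact < 0.01 & r1$p_avoid < 0.01, na.rm = TRUE))
  expect_warning(interaction_test(g, lab2, n_perm = 50, seed = 1), "coarse")
})

test_that("planted attraction and avoidance are detected", {
  att <- sim_config(width = 600, height = 600, n_cells = 400,
                    proportions = c(A = 0.4, B = 0.4, C = 0.2),
                    interactions = list(list(pair = c("A", "B"),
                                             mode = "attraction", scale_um = 4)))
  ca <- generate_cells(att, seed = 5)
  ga <- build_graph(ca$centroid_x_um, ca$centroid_y_um, 6)
  ra <- interaction_test(ga, ca$lineage, n_perm = 500, seed = 5)
  expect_equal(ra$call[ra$type_a == "A" & ra$type_b == "B"], "interact")
  avo <- sim_config(width = 500, height = 500, n_cells = 2000,
                    proportions = c(A = 0.5, B = 0.5),
                    interactions = list(list(pair = c("A", "B"),
                                             mode = "avoidance", hardcore_um = 8)))
  cv <- generate_cells(avo, seed = 6)
  gv <- build_graph(cv$centroid_x_um, cv$centroid_y_um, 6)
  rv <- interaction_test(gv, cv$lineage, n_perm = 500, seed = 6)
  expect_equal(rv$call[rv$type_a == "A" & rv$type_b == "B"], "avoid")
})

test_that("cohort heatmap scores are tallied fractions in [-1, 1]", {
  mk <- function(call) {
    structure(data.frame(type_a = "A", type_b = "B", observed = 1,
                         null_mean = 0, null_sd = 1, p_interact = 0.001,
                         p_avoid = 0.5, call = call, n_perm = 100,
                         stringsAsFactors = FALSE),
              class = c("interaction_result", "data.frame"))
  }
  expect_equal(cohort_heatmap(list(mk("interact"), mk("interact")))["A", "B"], 1)
  expect_equal(cohort_heatmap(list(mk("interact"), mk("avoid")))["A", "B"], 0)
  hm <- cohort_heatmap(list(mk("interact"), mk("avoid"), mk("ns"), mk("ns"),
                            mk(NA_character_)))
  expect_equal(hm["A", "B"], (1 - 1) / 4)  # NA call drops from the denominator
})

test_that("conditional contrasts split interacting vs avoiding focal cells", {
  # geometry: two A cells, one next to a B cell, one isolated
  cells <- cell_table(data.frame(
    cell_id = 1:3, image_id = "i",
    centroid_x_um = c(0, 3, 100), centroid_y_um = c(0, 0, 0),
    area_px = 10, lineage = c("A", "B", "A"),
    expr_Ki67 = c(8, 1, 2), expr_CC3 = c(2, 1, 2), stringsAsFactors = FALSE))
  g <- build_graph(cells$centroid_x_um, cells$centroid_y_um, 6)
  cc <- conditional_contrast(cells, g, "A", "B", statistic = "marker",
                             marker = "Ki67")
  expect_equal(cc$interacting, 8)
  expect_equal(cc$avoiding, 2)
  expect_false(cc$excluded)
  # ratio statistic uses the smallest positive CC3 as pseudocount
  cr <- conditional_contrast(cells, g, "A", "B", statistic = "ki67_cc3")
  expect_equal(cr$interacting, 8 / (2 + 1))
  # all focal cells interacting -> excluded
  cells2 <- cells; cells2$centroid_x_um[3] <- 5
  g2 <- build_graph(cells2$centroid_x_um, cells2$centroid_y_um, 6)
  expect_true(conditional_contrast(cells2, g2, "A", "B",
                                   statistic = "marker", marker = "Ki67")$excluded)
  # absent partner type -> excluded
  cells3 <- cells; cells3$lineage <- c("A", "A", "A")
  expect_true(conditional_contrast(cells3, g, "A", "B",
                                   statistic = "marker", marker = "Ki67")$excluded)
})

test_that("planted Ki67 suppression near partners is recovered across cohorts", {
  cfg <- sim_config(width = 600, height = 600, n_cells = 300,
                    proportions = c(Cancer = 0.6, Endothelial = 0.4),
                    functional = list(
                      list(marker = "Ki67", meanlog = 2, sdlog = 0.3,
                           modifier = list(focal = "Cancer", partner = "Endothelial",
                                           radius_um = 6, factor = 0.5)),
                      list(marker = "CC3", meanlog = 1, sdlog = 0.3)))
  hits <- 0
  for (co in 1:15) {
    int <- c(); avd <- c()
    for (i in 1:8) {
      cells <- generate_cells(cfg, seed = derive_seed(100, co, i))
      g <- build_graph(cells$centroid_x_um, cells$centroid_y_um, 6)
      cc <- conditional_contrast(cells, g, "Cancer", "Endothelial",
                                 statistic = "marker", marker = "Ki67")
      if (!cc$excluded) { int <- c(int, cc$interacting); avd <- c(avd, cc$avoiding) }
    }
    tst <- compare_groups(c(int, avd),
                          rep(c("int", "avd"), c(length(int), length(avd))))
    if (tst$p < 0.05 && mean(int) < mean(avd)) hits <- hits + 1
  }
  expect_gte(hits / 15, 0.9)
})

test_that("density categories map counts per mm^2 to none/low/high", {
  expect_equal(as.character(density_category(0, 1)$category), "none")
  expect_equal(density_category(0, 1)$display_count, 1)  # log-display convention
  expect_equal(as.character(density_category(3, 1)$category), "low")
  expect_equal(as.character(density_category(5, 1)$category), "low")
  expect_equal(as.character(density_category(6, 1)$category), "high")
  expect_equal(as.character(density_category(3, 0.25)$category), "high")
  expect_error(density_category(3, 0), "positive")
})
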