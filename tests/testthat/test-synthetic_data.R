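test_that("generation is fully deterministic under the master seed", {
  cfg <- test_config()
  a <- generate_image(cfg, seed = 99, image_id = "d")
  b <- generate_image(cfg, seed = 99, image_id = "d")
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$seg, b$seg)
  expect_identical(as.data.frame(a$cells), as.data.frame(b$cells))
  c2 <- generate_image(cfg, seed = 100, image_id = "d")
  expect_false(identical(a$stack$pixels, c2$stack$pixels))
  co1 <- generate_cohort(cfg, n_images = 4, n_patients = 3, seed = 5)
  co2 <- generate_cohort(cfg, n_images = 4, n_patients = 3, seed = 5)
  expect_identical(co1, co2)
})

test_that("type proportions are respected within sampling error", {
  cfg <- sim_config(width = 400, height = 400, n_cells = 500,
                    proportions = c(A = 0.5, B = 0.5))
  counts <- vapply(1:100, function(i)
    sum(null_image(cfg, seed = i)$lineage == "A"), numeric(1))
  # binomial(500, .5) 99.9% band for the mean of 100 draws
  expect_lt(abs(mean(counts) - 250), 4 * sqrt(250 * 0.5) / 10 + 4)
  # every realization within a generous binomial band
  expect_true(all(counts > 250 - 5 * sqrt(125) & counts < 250 + 5 * sqrt(125)))
})

test_that("planted attraction shortens nearest-partner distances below CSR", {
  att <- sim_config(width = 600, height = 600, n_cells = 400,
                    proportions = c(A = 0.5, B = 0.5),
                    interactions = list(list(pair = c("A", "B"),
                                             mode = "attraction", scale_um = 4)))
  csr <- sim_config(width = 600, height = 600, n_cells = 400,
                    proportions = c(A = 0.5, B = 0.5))
  nnd <- function(cells) {
    a <- cells$lineage == "A"; b <- cells$lineage == "B"
    d2 <- imcniche:::cross_dist2(
      cbind(cells$centroid_x_um, cells$centroid_y_um)[a, , drop = FALSE],
      cbind(cells$centroid_x_um, cells$centroid_y_um)[b, , drop = FALSE])
    mean(sqrt(apply(d2, 1, min)))
  }
  m_att <- mean(vapply(1:10, function(i) nnd(generate_cells(att, seed = i)),
                       numeric(1)))
  m_csr <- mean(vapply(1:10, function(i) nnd(null_image(csr, seed = i)),
                       numeric(1)))
  expect_lt(m_att, 0.8 * m_csr)  # clearly below the CSR expectation
})

test_that("hard-core avoidance keeps partners beyond the exclusion radius", {
  avo <- sim_config(width = 400, height = 400, n_cells = 1000,
                    proportions = c(A = 0.5, B = 0.5),
                    interactions = list(list(pair = c("A", "B"),
                                             mode = "avoidance", hardcore_um = 8)))
  cells <- generate_cells(avo, seed = 3)
  a <- cells$lineage == "A"; b <- cells$lineage == "B"
  xy <- cbind(cells$centroid_x_um, cells$centroid_y_um)
  d2 <- imcniche:::cross_dist2(xy[a, , drop = FALSE], xy[b, , drop = FALSE])
  expect_gt(sqrt(min(d2)), 8)
  expect_lt(sum(b), sum(a))  # thinning removes B cells
})

test_that("planted two-region compositions separate perfectly in window space", {
  cfg <- sim_config(width = 400, height = 400, n_cells = 400,
                    proportions = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                    regions = list(
                      list(x0 = 0, x1 = 199, y0 = 0, y1 = 400,
                           props = c(A = 0.6, B = 0.4)),
                      list(x0 = 199, x1 = 400, y0 = 0, y1 = 400,
                           props = c(C = 0.6, D = 0.4))))
  cells <- generate_cells(cfg, seed = 21)
  W <- neighbour_windows(cells$centroid_x_um, cells$centroid_y_um,
                         cells$lineage, N = 10,
                         type_levels = c("A", "B", "C", "D"))
  m <- fit_cn(W, K = 2, seed = 0)
  # near-perfect recovery; mismatches concentrate in the window-width
  # boundary strip between the regions
  expect_gte(adjusted_rand_index(m$labels, cells$region), 0.9)
})

test_that("rendered channels drive the matching panel to the planted lineages", {
  cfg <- test_config()
  im <- generate_image(cfg, seed = 1, image_id = "e2e")
  sp <- sim_panel(cfg)
  expect_equal(length(im$stack$channels), 3)  # Undefined gets no marker
  expect_true(all(im$stack$pixels == round(im$stack$pixels)))
  masks <- curate_masks(im$stack, sp$panel, seed = 2)
  cells <- phenotype_cells(im$seg, im$stack, masks, sp$hierarchy)
  expect_gte(mean(cells$lineage == im$cells$lineage), 0.9)
})

test_that("cohort generation allocates cores and draws hazard-linked survival", {
  cfg <- test_config()
  co <- generate_cohort(cfg, n_images = 6, n_patients = 4, seed = 11)
  expect_equal(length(unique(co$cells$patient_id)), 4)
  expect_equal(length(unique(co$cells$image_id)), 6)
  expect_equal(nrow(co$clinical), 4)
  expect_true(all(co$clinical$overall_survival_days > 0))
  expect_true(all(co$clinical$event %in% 0:1))
  # strong planted effect shows up as shorter survival for high-feature patients
  sv <- simulate_survival(c(rep(0, 100), rep(1, 100)), base_rate = 1 / 400,
                          beta = log(4), horizon_days = 1e6, seed = 2)
  expect_gt(mean(sv$overall_survival_days[1:100]),
            mean(sv$overall_survival_days[101:200]))
})

test_that("infeasible packing densities raise an informative error", {
  cfg <- sim_config(width = 60, height = 60, n_cells = 500,
                    proportions = c(A = 1), cell_radius_px = 4)
  expect_error(generate_image(cfg, seed = 1), "packing")
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(13)
  for (r in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
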