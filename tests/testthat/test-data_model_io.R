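panel3 <- marker_panel(data.frame(
  name = c("CD68", "GFAP", "CD31"),
  role = c("lineage", "lineage", "lineage")))

test_that("panel and hierarchy validation enforce the documented invariants", {
  expect_error(marker_panel(data.frame(name = c("A", "A"), role = "lineage")),
               "duplicate")
  expect_error(marker_panel(data.frame(name = "A", role = "lineage",
                                       foreground_level = 7)), "\\[1, 6\\]")
  expect_error(marker_panel(data.frame(name = "A", role = "functional")),
               "lineage")
  h <- lineage_hierarchy(list(Macrophage = "CD68", Astrocyte = "GFAP"), panel3)
  expect_s3_class(h, "lineage_hierarchy")
  expect_error(lineage_hierarchy(list(X = "NotAMarker"), panel3), "NotAMarker")
  expect_error(lineage_hierarchy(list(A = "CD68", A = "GFAP")), "duplicate")
})

test_that("panel and hierarchy YAML round-trips are faithful", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_panel(panel3, tmp)
  p2 <- read_panel(tmp)
  expect_equal(as.data.frame(p2), as.data.frame(panel3))
  h <- lineage_hierarchy(list(Macrophage = "CD68",
                              Vessel = c("CD31", "GFAP")), panel3)
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  write_hierarchy(h, tmp2)
  expect_equal(read_hierarchy(tmp2, panel3), h)
})

test_that("shipped example panel and hierarchy configs parse", {
  p <- read_panel(system.file("extdata", "example_panel.yaml",
                              package = "imcniche"))
  expect_equal(nrow(p), 8)
  expect_true(p$refine[p$name == "GFAP"])
  expect_true(p$enhance[p$name == "MPO"])
  h <- read_hierarchy(system.file("extdata", "example_hierarchy.yaml",
                                  package = "imcniche"), p)
  expect_equal(names(h)[1], "Macrophage")
})

test_that("channel stack TIFF round-trip is bit-exact and panel-checked", {
  set.seed(11)
  arr <- array(rpois(3 * 64 * 64, 40), dim = c(3, 64, 64))
  st <- channel_stack(arr, "img1", panel3$name)
  expect_equal(dim(st$pixels), c(3, 64, 64))
  tmp <- withr::local_tempfile(fileext = ".tiff")
  write_channel_stack(st, tmp)
  back <- read_channel_stack(tmp, panel3)
  expect_identical(back$pixels, st$pixels + 0)  # lossless round trip
  expect_equal(back$channels, panel3$name)
  # 2-channel image against a 3-marker panel names the absent marker
  st2 <- channel_stack(arr[1:2, , , drop = FALSE], "img2", panel3$name[1:2])
  tmp2 <- withr::local_tempfile(fileext = ".tiff")
  write_channel_stack(st2, tmp2)
  expect_error(read_channel_stack(tmp2, panel3), "CD31")
  # without a sidecar, order matching must be confirmed explicitly
  file.remove(paste0(tmp, ".channels.txt"))
  expect_error(read_channel_stack(tmp, panel3), "match_by_order")
  expect_identical(read_channel_stack(tmp, panel3, match_by_order = TRUE)$pixels,
                   st$pixels + 0)
})

test_that("segmentation masks round-trip bit-exact", {
  set.seed(2)
  seg <- matrix(sample(0:7, 48 * 32, replace = TRUE), 48, 32)
  tmp <- withr::local_tempfile(fileext = ".tiff")
  write_segmentation(seg, tmp)
  expect_identical(read_segmentation(tmp), seg)
})

test_that("cell table round-trip preserves all fields including optional columns", {
  df <- data.frame(cell_id = 1:10, image_id = "a",
                   centroid_x_um = runif(10, 0, 100),
                   centroid_y_um = runif(10, 0, 100),
                   area_px = sample(20:60, 10), lineage = "Tumour",
                   expr_CD68 = runif(10), cn_label = sample(1:3, 10, TRUE),
                   my_extra = letters[1:10], stringsAsFactors = FALSE)
  tab <- cell_table(df)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(tab, tmp)
  back <- read_cell_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_true("cn_label" %in% names(back))
  expect_true("my_extra" %in% names(back))
  expect_error(cell_table(df[setdiff(names(df), "centroid_x_um")]),
               "centroid_x_um")
  expect_error(cell_table(transform(df, expr_CD68 = -1)), "non-negative")
})

test_that("clinical join and per-patient averaging follow the averaging rule", {
  cells <- cell_table(data.frame(
    cell_id = 1:4, image_id = c("i1", "i1", "i2", "i3"),
    centroid_x_um = 1, centroid_y_um = 1, area_px = 10, lineage = "T",
    patient_id = c("p1", "p1", "p1", "p2"), stringsAsFactors = FALSE))
  clin <- clinical_table(data.frame(patient_id = c("p1", "p2"),
                                    overall_survival_days = c(100, 900),
                                    event = c(1, 0)))
  co <- attach_clinical(cells, clin)
  feats <- data.frame(image_id = c("i1", "i2", "i3"), f = c(10, 20, 7))
  avg <- average_by_patient(feats, co)
  expect_equal(avg$f[avg$patient_id == "p1"], 15)  # mean of two cores
  expect_equal(avg$f[avg$patient_id == "p2"], 7)   # single core unchanged
  # order invariance of the averaging
  avg2 <- average_by_patient(feats[c(3, 1, 2), ], co)
  expect_equal(avg, avg2)
  bad <- cells; bad$patient_id[4] <- "p9"
  expect_error(attach_clinical(bad, clin), "p9")
  expect_error(clinical_table(data.frame(patient_id = "p",
                                         overall_survival_days = -1, event = 1)),
               "positive")
})

test_that("validate_bundle checks image/mask/panel consistency", {
  dir <- withr::local_tempdir()
  arr <- array(rpois(3 * 16 * 16, 5), dim = c(3, 16, 16))
  st <- channel_stack(arr, "a", panel3$name)
  write_channel_stack(st, file.path(dir, "a_img.tiff"))
  write_segmentation(matrix(0L, 16, 16), file.path(dir, "a_seg.tiff"))
  res <- validate_bundle(dir, panel3)
  expect_equal(res$n_channels, 3)
  write_segmentation(matrix(0L, 8, 8), file.path(dir, "a_seg.tiff"))
  expect_error(validate_bundle(dir, panel3), "mismatch")
})
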