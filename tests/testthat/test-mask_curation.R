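test_that("median filter matches the brute-force sorted-median oracle", {
  expect_equal(median_filter_3x3(matrix(7, 6, 6)), matrix(7, 6, 6))
  hot <- matrix(0, 7, 7); hot[4, 4] <- 100
  expect_equal(median_filter_3x3(hot), matrix(0, 7, 7))
  set.seed(5)
  for (r in 1:5) {
    x <- matrix(sample(0:50, 25, replace = TRUE), 5, 5)
    expect_equal(median_filter_3x3(x), oracle_median3x3(x))
  }
  # non-square with replicated edges
  x <- matrix(runif(4 * 9), 4, 9)
  expect_equal(median_filter_3x3(x), oracle_median3x3(x))
})

test_that("level quantization handles exact, degenerate and bimodal inputs", {
  vals <- c(0, 10, 20, 30, 40, 50)
  ch <- matrix(rep(vals, each = 10), 10, 6)
  lv <- quantize_levels(ch, 6, seed = 1)
  expect_equal(lv$centres, vals)        # k equals support size: one level per value
  expect_equal(sort(unique(as.vector(lv$levels))), 1:6)
  expect_warning(lvc <- quantize_levels(matrix(3, 5, 5), 6, seed = 1),
                 "distinct")
  expect_equal(lvc$k, 1)
  expect_true(all(lvc$levels == 1))
  # overlapping bimodal mixture (data exist near the boundary, so the
  # optimal split is unique): boundary within 1 unit of the exhaustive
  # optimal 2-split
  set.seed(42)
  x <- c(rnorm(4000, 10, 2), rnorm(4000, 20, 2))
  ch2 <- matrix(x, 80, 100)
  lv2 <- quantize_levels(ch2, 2, seed = 3)
  b_fit <- mean(lv2$centres)
  # oracle: exhaustive search over all midpoints of consecutive sorted values
  xs <- sort(x)
  cuts <- (head(xs, -1) + xs[-1]) / 2
  cuts <- cuts[cuts > 8 & cuts < 22]
  lo_s <- cumsum(xs); lo_s2 <- cumsum(xs^2)
  tot <- sum(xs); tot2 <- sum(xs^2)
  idx <- findInterval(cuts, xs)
  ss <- (lo_s2[idx] - lo_s[idx]^2 / idx) +
    ((tot2 - lo_s2[idx]) - (tot - lo_s[idx])^2 / (length(xs) - idx))
  bsplit <- cuts[which.min(ss)]
  expect_lt(abs(b_fit - bsplit), 1)
})

test_that("foreground selection takes the brightest groups and is nested in L", {
  vals <- c(0, 10, 20, 30, 40, 50)
  ch <- matrix(rep(vals, each = 10), 10, 6)
  lv <- quantize_levels(ch, 6, seed = 1)
  expect_true(all(select_foreground(lv, 6)))
  f1 <- select_foreground(lv, 1)
  expect_equal(which(f1), which(ch == 50))
  expect_error(select_foreground(lv, 0), "\\[1, 6\\]")
  set.seed(9)
  for (r in 1:3) {
    ch <- matrix(rexp(900, 0.2), 30, 30)
    lv <- quantize_levels(ch, 6, seed = r)
    for (L in 1:5)
      expect_true(all(select_foreground(lv, L + 1)[select_foreground(lv, L)]))
  }
})

test_that("blob removal matches flood-fill enumeration and is idempotent", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE                 # area 4 blob
  m[8:17, 8:12] <- TRUE               # area 50 blob
  m[1, 20] <- TRUE                    # singleton
  out <- remove_small_blobs(m, 10)
  expect_equal(sum(out), 50)
  expect_equal(remove_small_blobs(m, 1), m)
  set.seed(21)
  for (r in 1:5) {
    rm_ <- matrix(runif(400) < 0.4, 20, 20)
    got <- remove_small_blobs(rm_, 5)
    lab <- oracle_components(rm_, 8)
    keep <- which(tabulate(lab[lab > 0]) >= 5)
    expect_equal(got, matrix(lab %in% keep, 20, 20))
    expect_equal(remove_small_blobs(got, 5), got)  # idempotent
  }
})

test_that("adaptive refinement is the AND of mask and local-mean threshold", {
  set.seed(3)
  ch <- matrix(rexp(64 * 64, 0.5), 64, 64)
  empty <- matrix(FALSE, 64, 64)
  expect_equal(adaptive_refine(ch, empty), empty)
  full <- matrix(TRUE, 64, 64)
  ref <- adaptive_refine(ch, full, sensitivity = 0.4)
  # independent recomputation of the adaptive operand (double loop local mean)
  half <- floor(64 / 16)
  lm <- ch
  for (i in 1:64) for (j in 1:64) {
    ii <- max(1, i - half):min(64, i + half)
    jj <- max(1, j - half):min(64, j + half)
    lm[i, j] <- mean(ch[ii, jj])
  }
  adap <- ch > 0.6 * lm
  expect_equal(ref, adap)
  msk <- matrix(runif(64 * 64) < 0.5, 64, 64)
  expect_equal(adaptive_refine(ch, msk), msk & adap)
  expect_true(all(msk[adaptive_refine(ch, msk)]))  # result within input mask
})

test_that("contrast enhancement clips percentiles and preserves interior ranks", {
  set.seed(8)
  x <- matrix(runif(400, 0, 10), 20, 20)
  expect_equal(enhance_contrast(x, 0, 100), x)
  y <- x; y[1, 1] <- 1e5
  out <- enhance_contrast(y, 1, 99)
  expect_equal(out[1, 1], unname(quantile(y, 0.99)))  # outlier clipped to P99
  expect_lt(out[1, 1], 1e5)
  p <- quantile(x, c(0.05, 0.95))
  interior <- x > p[1] & x < p[2]
  out2 <- enhance_contrast(x, 5, 95)
  expect_equal(cor(rank(x[interior]), rank(out2[interior])), 1)
  expect_warning(enhance_contrast(matrix(2, 4, 4)), "constant")
})

test_that("mask curation composes the step operations and recovers planted signal", {
  params <- list(foreground_level = 5L, min_blob_area = 5L, refine = FALSE,
                 enhance = FALSE, sensitivity = 0.4, low_pct = 1, high_pct = 99)
  zero <- matrix(0, 40, 40)
  expect_warning(mz <- curate_mask(zero, params, seed = 1), "distinct")
  expect_false(any(mz))
  # planted bright square over exponential background
  set.seed(14)
  ch <- matrix(round(rexp(150 * 150, 1 / 0.3)), 150, 150)
  region <- matrix(FALSE, 150, 150); region[40:110, 50:120] <- TRUE
  ch[region] <- ch[region] + round(rlnorm(sum(region), 3, 0.4))
  m <- curate_mask(ch, params, seed = 2)
  expect_gt(sum(m & region) / sum(region), 0.95)    # sensitivity
  expect_lt(sum(m & !region) / sum(!region), 0.02)  # false positives
  # equals manual sequential application of the step operations
  chf <- median_filter_3x3(ch)
  lv <- quantize_levels(chf, 6, seed = 2)
  manual <- remove_small_blobs(select_foreground(lv, 5), 5)
  expect_equal(m, manual)
})

test_that("curation is shift-invariant when enhancement is off", {
  params <- list(foreground_level = 2L, min_blob_area = 4L, refine = FALSE,
                 enhance = FALSE)
  set.seed(31)
  ch <- matrix(round(rexp(60 * 60, 0.2)), 60, 60)
  m1 <- curate_mask(ch, params, seed = 5)
  m2 <- curate_mask(ch + 17, params, seed = 5)
  expect_equal(m1, m2)
})
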