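test_that("classify_pixel reproduces the hand-computed HSI example and gate cases", {
  cfg <- ppc_config(hue_center = 0.05, hue_width = 0.15, saturation_min = 0,
                    i_sp_hi = 60, i_p_hi = 65, i_wp_hi = 80)
  # brown-ish DAB pixel: hue ~0.083, intensity 70 -> weak
  expect_equal(as.character(classify_pixel(120, 70, 20, cfg)), "weak")
  # white: passes saturation gate but intensity 255 > 80 -> negative
  expect_equal(as.character(classify_pixel(255, 255, 255, cfg)), "negative")
  # blue: hue mismatch -> negative regardless of intensity
  expect_equal(as.character(classify_pixel(20, 20, 200, cfg)), "negative")
  # black: saturation undefined -> negative by convention
  expect_equal(as.character(classify_pixel(0, 0, 0, cfg)), "negative")
  # intensity bin boundaries
  expect_equal(as.character(classify_pixel(90, 50, 10, cfg)), "strong")   # I = 50
  expect_equal(as.character(classify_pixel(110, 60, 16, cfg)), "medium")  # I = 62
  expect_equal(as.character(classify_pixel(140, 80, 25, cfg)), "negative") # I ~ 81.7
  expect_error(classify_pixel(300, 0, 0, cfg), class = "crossproteo_param_error")
  expect_error(ppc_config(i_sp_hi = 90, i_wp_hi = 80), class = "crossproteo_param_error")
})

test_that("classify_pixel agrees with a straight-from-definition oracle on random pixels", {
  set.seed(123)
  n <- 10000
  r <- sample(0:255, n, TRUE); g <- sample(0:255, n, TRUE); b <- sample(0:255, n, TRUE)
  cfg <- ppc_config()
  got <- as.character(classify_pixel(r, g, b, cfg))
  want <- vapply(seq_len(n), function(i) oracle_classify(r[i], g[i], b[i], cfg), "")
  expect_identical(got, want)
})

test_that("percent positive area is exact on planted images and averages over ROIs", {
  g <- gen_stain_image(100, 100, positive_fraction = 0.25, seed = 31)
  res <- percent_positive(g$image, list(full = g$roi_mask))
  expect_equal(res$per_roi$n_total, 10000)
  expect_equal(res$per_roi$n_strong + res$per_roi$n_medium + res$per_roi$n_weak, 2500)
  expect_equal(res$case_value, 25.0)
  # class counts partition the ROI
  with(res$per_roi, expect_equal(n_strong + n_medium + n_weak + n_negative, n_total))
  # all-negative image
  g0 <- gen_stain_image(50, 50, positive_fraction = 0, seed = 32)
  expect_equal(percent_positive(g0$image, list(full = g0$roi_mask))$case_value, 0)
  # two ROIs with 10% and 30% -> case mean 20%
  roi1 <- matrix(FALSE, 60, 60); roi1[1:30, 1:30] <- TRUE
  roi2 <- matrix(FALSE, 60, 60); roi2[31:60, 31:60] <- TRUE
  ga <- gen_stain_image(60, 60, 0.1, roi_mask = roi1, seed = 33)
  gb <- gen_stain_image(60, 60, 0.3, roi_mask = roi2, seed = 34)
  img <- ga$image
  img[rep(roi2, 3)] <- gb$image[rep(roi2, 3)]
  res2 <- percent_positive(img, list(CA1 = roi1, CA2 = roi2))
  expect_equal(res2$per_roi$percent_positive, c(10, 30))
  expect_equal(res2$case_value, 20)
  # empty ROI skipped with warning
  expect_warning(res3 <- percent_positive(g$image, list(e = matrix(FALSE, 100, 100),
                                                        f = g$roi_mask)), "empty")
  expect_equal(res3$case_value, 25.0)
})

test_that("quantification is invariant to joint translation of image and mask", {
  roi <- matrix(FALSE, 40, 40); roi[5:20, 5:20] <- TRUE
  g <- gen_stain_image(40, 40, 0.4, roi_mask = roi, seed = 35)
  shift <- function(m, d) {
    out <- array(rep(c(70, 70, 190), each = dim(m)[1] * dim(m)[2]), dim(m))
    out[(1 + d):dim(m)[1], (1 + d):dim(m)[2], ] <-
      m[1:(dim(m)[1] - d), 1:(dim(m)[2] - d), ]
    out
  }
  img2 <- shift(g$image, 10)
  roi2 <- matrix(FALSE, 40, 40); roi2[15:30, 15:30] <- TRUE
  p1 <- percent_positive(g$image, list(r = roi))$case_value
  p2 <- percent_positive(img2, list(r = roi2))$case_value
  expect_equal(p1, p2)
})

test_that("round-trip through PNG files preserves the quantification", {
  png_path <- withr::local_tempfile(fileext = ".png")
  mask_path <- withr::local_tempfile(fileext = ".png")
  g <- gen_stain_image(64, 64, 0.2, seed = 36, out_png = png_path, out_mask = mask_path)
  res <- percent_positive(png_path, list(full = mask_path))
  expect_equal(res$case_value, g$answer_key$percent_positive)
})

test_that("compare_groups reports fold changes and two-sided tests", {
  fc <- compare_groups(c(2, 2, 2), c(1, 1, 1))
  expect_equal(fc$fold_change, 2.0)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(compare_groups(c(1, 2), c(0, 0))$fold_change, NA_real_)
  mw <- compare_groups(c(5, 6, 7), c(1, 2, 3), test = "mann_whitney")
  expect_lt(mw$p, 0.2)
  expect_error(compare_groups(1, c(1, 2)), class = "crossproteo_param_error")
})
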