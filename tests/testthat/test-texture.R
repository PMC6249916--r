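test_that("quantization bins in-mask intensities into equal-width levels", {
  img <- roi_image(matrix(7, 4, 4), matrix(TRUE, 4, 4))
  expect_true(all(quantize_roi(img, 32)$levels == 1))

  img <- roi_image(matrix(0:31, 4, 8), matrix(TRUE, 4, 8))
  q <- quantize_roi(img, 32)
  expect_equal(as.vector(q$levels), as.vector(matrix(0:31, 4, 8)) + 1)

  img <- roi_image(matrix(c(0, 10, 20, 30), 2, 2), matrix(TRUE, 2, 2))
  expect_equal(sort(as.vector(quantize_roi(img, 2)$levels)), c(1, 1, 2, 2))

  expect_error(quantize_roi(img, 1), "at least 2")
  expect_error(roi_image(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("first-order features match hand arithmetic and conventions", {
  img <- roi_image(matrix(7, 3, 3), matrix(TRUE, 3, 3))
  f <- first_order_features(img, quantize_roi(img, 32))
  expect_equal(unname(f[c("fo_mean", "fo_variance", "fo_entropy",
                          "fo_uniformity", "fo_skewness", "fo_kurtosis")]),
               c(7, 0, 0, 1, 0, 0))

  img <- roi_image(matrix(1:4, 2, 2), matrix(TRUE, 2, 2))
  f <- first_order_features(img, quantize_roi(img, 4))
  expect_equal(unname(f["fo_entropy"]), 2)
  expect_equal(unname(f["fo_uniformity"]), 0.25)

  img <- roi_image(matrix(c(1, 1, 1, 5), 2, 2), matrix(TRUE, 2, 2))
  f <- first_order_features(img, quantize_roi(img, 4))
  expect_equal(unname(f[c("fo_mean", "fo_variance", "fo_range")]), c(2, 3, 4))
})

test_that("co-occurrence matrix matches the worked toy and stays normalized", {
  img <- roi_image(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE),
                   matrix(TRUE, 2, 2))
  P <- glcm(quantize_roi(img, 2), c(0, 1))
  expect_equal(unclass(P)[1:2, 1:2],
               matrix(c(0.5, 0.25, 0.25, 0), 2, 2), ignore_attr = TRUE)

  cst <- roi_image(matrix(3, 4, 4), matrix(TRUE, 4, 4))
  P <- glcm(quantize_roi(cst, 8), c(1, 1))
  expect_equal(sum(P), 1)
  expect_equal(unclass(P)[1, 1], 1)

  expect_error(glcm(quantize_roi(cst, 8), c(0, 0)), "nonzero")
})

test_that("co-occurrence matrices equal brute-force pair counting", {
  withr::with_seed(101, {
    offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
    for (i in 1:100) {
      img <- random_toy_image(sample(2:8, 1), sample(2:8, 1))
      ng <- sample(2:6, 1)
      q <- quantize_roi(img, ng)
      for (o in offs) {
        expect_equal(unclass(glcm(q, o)), glcm_oracle(q$levels, ng, o),
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("Haralick features match direct summation on the worked toy", {
  P <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  h <- haralick_features(P)
  expect_equal(unname(h["glcm_energy"]), 0.375)
  expect_equal(unname(h["glcm_contrast"]), 0.5)
  expect_equal(unname(h["glcm_entropy"]), 1.5)

  # independent direct-summation check of the remaining descriptors
  i <- row(P); j <- col(P)
  expect_equal(unname(h["glcm_idm"]), sum(P / (1 + (i - j)^2)))
  px <- rowSums(P); mx <- sum(1:2 * px)
  expect_equal(unname(h["glcm_variance"]), sum((i - mx)^2 * P))

  single <- matrix(0, 3, 3); single[2, 2] <- 1
  h <- haralick_features(single)
  expect_equal(unname(h[c("glcm_contrast", "glcm_energy", "glcm_entropy",
                          "glcm_correlation")]), c(0, 1, 0, 1))

  withr::with_seed(7, {
    for (i in 1:20) {
      M <- matrix(stats::runif(16), 4, 4); M <- (M + t(M)); M <- M / sum(M)
      h <- haralick_features(M)
      expect_gte(unname(h["glcm_entropy"]), 0)
      expect_true(h["glcm_energy"] > 0 && h["glcm_energy"] <= 1)
    }
  })
})

test_that("run-length matrices match exhaustive run enumeration", {
  img <- roi_image(matrix(c(1, 1, 2), 1, 3), matrix(TRUE, 1, 3))
  R <- glrlm(quantize_roi(img, 2), c(0, 1))
  expect_equal(unclass(R), matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)

  cst <- roi_image(matrix(1, 1, 5), matrix(TRUE, 1, 5))
  R <- glrlm(quantize_roi(cst, 4), c(0, 1))
  expect_equal(unclass(R)[1, 5], 1)
  expect_equal(sum(R), 1)

  withr::with_seed(202, {
    dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
    for (i in 1:100) {
      img <- random_toy_image(sample(2:8, 1), sample(2:8, 1))
      ng <- sample(2:5, 1)
      q <- quantize_roi(img, ng)
      for (d in dirs) {
        R <- unclass(glrlm(q, d))
        O <- glrlm_oracle(q$levels, ng, d)
        expect_equal(R, O[, seq_len(ncol(R)), drop = FALSE],
                     ignore_attr = TRUE)
        expect_equal(sum(O[, seq_len(ncol(O))] * col(O)), sum(q$levels > 0))
      }
    }
  })
})

test_that("run-length features match the two-run worked example", {
  img <- roi_image(matrix(c(1, 1, 2), 1, 3), matrix(TRUE, 1, 3))
  f <- glrlm_features(glrlm(quantize_roi(img, 2), c(0, 1)))
  expect_equal(unname(f["glrlm_sre"]), 0.625)
  expect_equal(unname(f["glrlm_rp"]), 2 / 3)

  # all runs length 1: both emphases hit their limit
  img <- roi_image(matrix(c(1, 2, 1, 2), 1, 4), matrix(TRUE, 1, 4))
  f <- glrlm_features(glrlm(quantize_roi(img, 2), c(0, 1)))
  expect_equal(unname(f["glrlm_sre"]), 1)
  expect_equal(unname(f["glrlm_lre"]), 1)

  # single run
  img <- roi_image(matrix(1, 1, 4), matrix(TRUE, 1, 4))
  f <- glrlm_features(glrlm(quantize_roi(img, 2), c(0, 1)))
  expect_equal(unname(f["glrlm_gln"]), 1)
})

test_that("default catalog yields 110 named finite features, deterministically", {
  cat110 <- feature_catalog()
  expect_equal(nrow(cat110), 110)
  expect_equal(sum(cat110$family == "first_order"), 14)
  expect_equal(sum(cat110$family == "glcm"), 52)
  expect_equal(sum(cat110$family == "glrlm"), 44)

  withr::with_seed(5, {
    img <- random_toy_image(32, 32)
    v1 <- extract_features(img)
    v2 <- extract_features(img)
    expect_identical(v1, v2)
    expect_length(v1, 110)
    expect_identical(names(v1), cat110$name)
  })
})

test_that("all 110 features are finite on degenerate ROIs", {
  cases <- list(
    constant = roi_image(matrix(7, 8, 8), matrix(TRUE, 8, 8)),
    one_pixel = roi_image(matrix(5, 1, 1), matrix(TRUE, 1, 1)),
    checkerboard = {
      m <- matrix(0, 8, 8)
      roi_image((row(m) + col(m)) %% 2, matrix(TRUE, 8, 8))
    })
  for (nm in names(cases)) {
    v <- extract_features(cases[[nm]])
    expect_true(all(is.finite(v)), label = paste("finite on", nm))
    expect_length(v, 110)
  }
})

test_that("rotating the image permutes direction-indexed features only", {
  withr::with_seed(11, {
    px <- matrix(stats::rnorm(256), 16, 16)
    mk <- matrix(stats::runif(256) > 0.3, 16, 16)
    mk[8, 8] <- TRUE
    v1 <- extract_features(roi_image(px, mk))
    rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
    v2 <- extract_features(roi_image(rot(px), rot(mk)))
    fo <- grepl("^fo_", names(v1))
    expect_equal(v1[fo], v2[fo], tolerance = 1e-12)
    expect_equal(sort(unname(v1[!fo])), sort(unname(v2[!fo])),
                 tolerance = 1e-9)
  })
})

test_that("additive noise increases mean co-occurrence entropy", {
  withr::with_seed(33, {
    ent <- matrix(NA_real_, 100, 3)
    for (i in 1:100) {
      base <- generate_texture_image(
        list(corr_len = 3, noise_var = 1, mean = 100), 24)
      for (k in 1:3) {
        s <- c(0, 0.7, 2)[k]
        noisy <- roi_image(
          base$pixels + stats::rnorm(length(base$pixels), sd = s),
          base$mask)
        ent[i, k] <- extract_features(noisy)[["glcm_entropy_0_1"]]
      }
    }
    expect_true(all(diff(colMeans(ent)) > 0))
  })
})
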