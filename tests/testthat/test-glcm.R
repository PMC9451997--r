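test_that("quantization bins the observed range uniformly", {
  img <- matrix(0:255, 16, 16)
  expect_identical(quantize_image(img, 256), img)
  expect_true(all(quantize_image(matrix(7L, 4, 4), 8) == 0))
  q8 <- quantize_image(img, 8)
  expect_identical(as.vector(q8), as.integer(floor((0:255) * 8 / 256)))
  expect_equal(max(q8), 7)
})

test_that("the cooccurrence counting convention matches the worked cells", {
  # one horizontally contiguous (1,1) pair and two (1,2)/(2,1) pairs
  img <- matrix(c(0, 1, 1, 0, 1, 2, 0, 2, 1), nrow = 1)
  p <- glcm_params(levels = 3, distance = 1, angles = 0)
  g <- compute_glcm(img, p, 0)
  expect_equal(g$counts[2, 2], 1) # M(1,1) = 1
  expect_equal(g$counts[2, 3], 2) # M(1,2) = 2
  expect_equal(g$counts[3, 2], 2) # M(2,1) = 2
  # the conventional add-transpose matrix doubles the diagonal instead
  p2 <- glcm_params(levels = 3, distance = 1, angles = 0,
                    counting = "ordered-symmetric")
  g2 <- compute_glcm(img, p2, 0)
  expect_equal(g2$counts[2, 2], 2)
  expect_equal(g2$counts[2, 3], 2)
  # 2x2 constant image: two horizontal pairs on the diagonal
  g3 <- compute_glcm(matrix(0L, 2, 2), glcm_params(levels = 2, angles = 0), 0)
  expect_equal(g3$counts[1, 1], 2)
})

test_that("GLCMs are symmetric and conserve pair counts", {
  for (seed in 1:10) {
    img <- with_seed_test(seed, matrix(sample(0:7, 96, replace = TRUE),
                                       8, 12))
    for (counting in c("paper", "ordered-symmetric")) {
      for (ang in c(0, 45, 90, 135)) {
        p <- glcm_params(levels = 8, distance = 1, angles = ang,
                         counting = counting)
        g <- compute_glcm(img, p, ang)
        expect_identical(g$counts, t(g$counts))
        diag_pairs <- sum(diag(g$counts))
        expected_total <- if (counting == "paper") {
          2 * g$n_pairs - diag_pairs
        } else {
          2 * g$n_pairs
        }
        expect_equal(sum(g$counts), expected_total)
      }
    }
  }
  # offset larger than the image errors out
  expect_error(compute_glcm(matrix(0L, 3, 3),
                            glcm_params(levels = 2, distance = 5,
                                        angles = 0), 0),
               "extent")
})

test_that("normalization yields a probability matrix and demands pairs", {
  img <- matrix(c(0, 1, 1, 0, 1, 2, 0, 2, 1), nrow = 1)
  g <- normalize_glcm(compute_glcm(img, glcm_params(3, 1, 0), 0))
  expect_equal(sum(g$normalized), 1, tolerance = 1e-12)
  expect_equal(g$normalized, g$counts / sum(g$counts))
  expect_error(normalize_glcm(matrix(0, 2, 2)), "zero pair")
  # round trip: scaling the probabilities back to counts and renormalizing
  # is idempotent
  expect_equal(normalize_glcm(g$normalized * sum(g$counts)), g$normalized)
})

test_that("texture features match analytic values on degenerate inputs", {
  p <- matrix(0, 4, 4); p[1, 1] <- 1
  f <- compute_features(p, degenerate_correlation = "zero")
  expect_equal(unname(f[c("energy", "contrast", "entropy",
                          "local_stability")]),
               c(1, 0, 0, 1))
  expect_equal(unname(f["mean"]), 0)
  # uniform GLCM: entropy = 2 log2 L, energy = 1 / L^2
  for (L in c(4, 8)) {
    u <- matrix(1 / L^2, L, L)
    fu <- compute_features(u)
    expect_equal(unname(fu["entropy"]), 2 * log2(L))
    expect_equal(unname(fu["energy"]), 1 / L^2)
  }
  expect_error(compute_features(matrix(0.5, 2, 2)), "sum to 1")
  expect_error(compute_features(p, degenerate_correlation = "error"),
               "undefined")
  expect_equal(unname(compute_features(p,
                                       degenerate_correlation = "zero")[
                                         "correlation"]), 0)
})

test_that("features agree with a double-loop evaluation", {
  for (seed in 1:25) {
    L <- with_seed_test(seed, sample(3:10, 1))
    p <- random_prob_matrix(L, seed + 500)
    got <- compute_features(p)
    want <- features_by_double_loop(p)
    expect_equal(got, want, tolerance = 1e-12)
    # bounds
    expect_gte(got[["energy"]], 1 / L^2 - 1e-12)
    expect_lte(got[["energy"]], 1)
    expect_gte(got[["entropy"]], 0)
    expect_lte(got[["entropy"]], 2 * log2(L) + 1e-12)
  }
})

test_that("image-level extraction is symmetric, composable and shift-invariant", {
  img <- with_seed_test(3, matrix(sample(0:255, 400, replace = TRUE), 20, 20))
  p0 <- glcm_params(levels = 8, distance = 1, angles = 0)
  p90 <- glcm_params(levels = 8, distance = 1, angles = 90)
  f_img_0 <- extract_image_features(img, p0)
  f_t_90 <- extract_image_features(t(img), p90)
  expect_equal(f_img_0, f_t_90, tolerance = 1e-12)
  # single-angle request equals the direct per-angle computation
  q <- quantize_image(img, 8)
  direct <- compute_features(normalize_glcm(compute_glcm(q, p0, 0)),
                             degenerate_correlation = "zero")
  expect_equal(f_img_0, direct, tolerance = 1e-12)
  # global gray shift leaves quantized features unchanged
  expect_equal(extract_image_features(img + 17L, p0), f_img_0,
               tolerance = 1e-12)
  # checkerboard has strictly higher contrast than a constant image
  chk <- matrix(rep_len(c(0L, 255L), 64), 8, 8)
  const <- matrix(100L, 8, 8)
  pall <- glcm_params(levels = 8, distance = 1)
  expect_gt(extract_image_features(chk, pall)[["contrast"]],
            extract_image_features(const, pall)[["contrast"]])
})
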