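test_that("min-max normalization handles identity, constant and affine cases", {
  ramp <- matrix(seq(0, 1, length.out = 16), 4)
  expect_equal(normalize_image(ramp), ramp)
  expect_true(all(normalize_image(matrix(7, 4, 4)) == 0))
  expect_equal(as.vector(normalize_image(matrix(c(10, 20, 30), 1))), c(0, 0.5, 1))
  expect_error(normalize_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("block exposure fitness and classification follow the 0.65 rule", {
  expect_equal(block_exposure_fitness(matrix(0, 4, 4)), 0)
  expect_equal(block_exposure_fitness(matrix(0.5, 4, 4)), 0.5)
  f <- block_exposure_fitness(matrix(0.7, 4, 4))
  expect_equal(f, 0.7)
  expect_equal(classify_exposure(f), "over_exposed")
  expect_equal(classify_exposure(0.5), "well_exposed")
  expect_equal(classify_exposure(0.65), "well_exposed")  # boundary stays well-exposed
  expect_equal(classify_exposure(0.66), "over_exposed")
  expect_error(classify_exposure(1.2), "must be in")
  # optional deviation term raises the fitness of high-contrast blocks
  blk <- matrix(c(0.2, 0.8), 4, 4)
  expect_gt(block_exposure_fitness(blk, lambda_c = 1), block_exposure_fitness(blk))
})

test_that("the multi-scale exposure matrix flags over-exposed regions", {
  expect_true(all(exposure_matrix(matrix(0.9, 32, 32))$mask))
  expect_false(any(exposure_matrix(matrix(0.3, 32, 32))$mask))

  # half bright / half dark: mask follows the bright half away from the seam
  img <- cbind(matrix(0.95, 32, 16), matrix(0.30, 32, 16))
  em <- exposure_matrix(img)
  expect_true(all(em$mask[, 1:8]))
  expect_false(any(em$mask[, 25:32]))

  # default weights are 1/n renormalized and decreasing
  w <- em$scale_weights
  expect_equal(w, (1 / c(2, 4, 6, 8)) / sum(1 / c(2, 4, 6, 8)))
  expect_true(all(diff(w) < 0))
  expect_error(exposure_matrix(matrix(0.5, 4, 4)), "smaller than the largest block")
  expect_error(exposure_matrix(matrix(2, 32, 32)), "normalized")
})

test_that("a uniform image is classified consistently at every block scale", {
  for (v in c(0.2, 0.5, 0.9)) {
    em <- exposure_matrix(matrix(v, 32, 32))
    # all-scale agreement means the weighted score is 0 or 1 (up to the
    # floating-point sum of the weights)
    expect_true(all(pmin(abs(em$map), abs(em$map - 1)) < 1e-12))
  }
})

test_that("attention maps carry exactly the two configured weights", {
  em_true <- exposure_matrix(matrix(0.9, 32, 32))
  em_false <- exposure_matrix(matrix(0.3, 32, 32))
  expect_true(all(attention_map(em_true)$a == 0.1))
  expect_true(all(attention_map(em_false)$a == 1.0))
  checker <- em_true
  checker$mask <- matrix(c(TRUE, FALSE), 32, 32)
  a <- attention_map(checker)
  expect_identical(sort(unique(as.vector(a$a))), c(0.1, 1.0))
  expect_true(all((a$a == 0.1) == checker$mask))
  expect_error(attention_map(em_true, low = 1, high = 0.1), "smaller")
})

test_that("initial illumination is the channel max, truncated where over-exposed", {
  img <- matrix(0.4, 32, 32)
  em <- exposure_matrix(img)
  expect_equal(init_illumination(img, em), img)  # no truncation

  # a saturated patch in a mildly varying background is capped near the
  # well-exposed 95th percentile
  set.seed(2)
  img2 <- matrix(runif(32 * 32, 0.35, 0.45), 32)
  img2[13:20, 13:20] <- 1.0
  em2 <- exposure_matrix(img2)
  expect_true(em2$mask[16, 16])
  l0 <- init_illumination(img2, em2)
  expect_lte(l0[16, 16], quantile(img2[!em2$mask], 0.95) + 1e-12)
})

test_that("total variation is zero on flats, counts steps, and is homogeneous", {
  expect_equal(tv_norm(matrix(3, 8, 8)), 0)
  step <- cbind(matrix(0, 10, 5), matrix(2.5, 10, 5))  # height 2.5 across 10 rows
  expect_equal(tv_norm(step), 2.5 * 10)
  l <- matrix(runif(64), 8)
  expect_equal(tv_norm(-3 * l), 3 * tv_norm(l))
})

test_that("illumination refinement has a monotone loss and smooths its input", {
  # fidelity-only: converges to the projection of L0
  img <- matrix(0.3, 16, 16)
  set.seed(4)
  l0 <- matrix(runif(256, 0.2, 0.9), 16)
  est <- refine_illumination(img, l0, lambda_tv = 0, iters = 200, step = 0.2)
  proj <- pmin(pmax(l0, img), 1)
  expect_lt(max(abs(est$l - proj)), 1e-4)

  # uniform image stays uniform
  estu <- refine_illumination(matrix(0.5, 16, 16), matrix(0.5, 16, 16))
  expect_lt(tv_norm(estu$l), 1e-8)

  # noisy initialization gets smoother, with a non-increasing loss trace
  noisy <- pmin(pmax(0.5 + matrix(rnorm(256, sd = 0.15), 16), 0.05), 1)
  est2 <- refine_illumination(matrix(0.05, 16, 16), noisy, lambda_tv = 0.15)
  expect_lte(tv_norm(est2$l), tv_norm(noisy))
  expect_true(all(diff(est2$loss_trace) <= 1e-12))
})

test_that("enhancement boosts dark regions and spares saturated ones", {
  fx <- lowlight_fixture(64, seed = 1)
  out <- enhance(fx$image)
  gain <- function(o, idx) mean(o$data[idx]) / mean(fx$image[idx])
  expect_gt(gain(out, fx$dark), 1)                # dark half strictly brighter
  expect_lt(gain(out, fx$bright), 1.05)           # saturated half nearly unchanged
  expect_true(all(out$data >= 0 & out$data <= 1))

  # ablation: attention improves the dark/saturated gain ratio
  out_uni <- enhance(fx$image, enhance_config(use_attention = FALSE))
  expect_gt(gain(out, fx$dark) / gain(out, fx$bright),
            gain(out_uni, fx$dark) / gain(out_uni, fx$bright))
})

test_that("a well-exposed uniform image maps to its analytic Retinex value", {
  # L converges to the input level, so R = v / v^gamma = v^(1 - gamma)
  v <- 0.5
  out <- enhance(matrix(v, 32, 32))
  expect_equal(mean(out$data), v^(1 - 0.8), tolerance = 1e-3)
  expect_lt(diff(range(out$data)), 1e-6)  # stays uniform
})

test_that("enhancement output stays in [0, 1] on random inputs and saturates", {
  set.seed(9)
  for (rep in 1:25) {
    img <- matrix(runif(24 * 24), 24)
    out <- enhance(img, enhance_config(iters = 30L))
    expect_true(all(out$data >= 0 & out$data <= 1))
  }
  # repeated enhancement converges rather than diverging
  fx <- lowlight_fixture(48, seed = 2)
  e1 <- enhance(fx$image)
  e2 <- enhance(e1$data)
  d1 <- abs(mean(e1$data) - mean(fx$image))
  d2 <- abs(mean(e2$data) - mean(e1$data))
  expect_lt(d2, d1)
})
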