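test_that("the central region implements the quarter-diameter rule", {
  roi <- central_roi(c(64, 64), 80)
  expect_equal(roi$radius, 10)  # diameter 20 for an 80 px lens
  expect_error(central_roi(c(10, 10), 7), class = "microlens_validation_error")

  # the region is concentric with and strictly inside the lens disc
  expect_equal(roi$center, c(64, 64))
  expect_lt(roi$radius, 40)
})

test_that("region means match brute-force pixel enumeration", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  roi <- central_roi(c(30.5, 20.5), 48)
  got <- roi_mean_grey(img, roi)
  # enumeration oracle
  acc <- 0; n <- 0
  for (x in 1:64) for (y in 1:64) {
    if ((x - 30.5)^2 + (y - 20.5)^2 <= 6^2) {
      acc <- acc + img[y, x]; n <- n + 1
    }
  }
  expect_equal(got, acc / n, tolerance = 1e-9)

  expect_equal(roi_mean_grey(matrix(100, 10, 10), disc_region(c(5, 5), 3)), 100)
  # half-dark / half-bright region symmetric about the disc centre
  half <- rbind(matrix(0, 5, 10), matrix(200, 5, 10))
  expect_equal(roi_mean_grey(half, disc_region(c(5.5, 5.5), 2)), 100)
  expect_error(roi_mean_grey(img, disc_region(c(200, 200), 2)),
               class = "microlens_empty_region_error")
})

test_that("stack measurement recovers planted optical parameters", {
  # blank field: both ratios are exactly 1
  st <- simulate_focal_stack(transmittance = 1, focus_gain = 0, noise_sd = 0)
  m <- measure_stack(st)
  expect_equal(m$transmittance_ratio, 1)
  expect_equal(m$focus_ratio, 1)

  # planted transmittance is recovered exactly without noise
  for (tr in c(0.5, 0.8, 1.0)) {
    st <- simulate_focal_stack(transmittance = tr, noise_sd = 0)
    expect_equal(measure_stack(st)$transmittance_ratio, tr)
  }

  # the focal plane wins and the focus ratio follows the generator's closed form
  st <- simulate_focal_stack(focus_gain = 1.5, noise_sd = 0)
  m <- measure_stack(st)
  expect_equal(m$focal_plane_index, 3L)
  expect_equal(m$focal_z, st$truth$focal_distance)
  roi <- central_roi(st$lens_center, st$lens_diameter)
  n_px <- sum((matrix(1:128, 128, 128, byrow = TRUE) - st$lens_center[1])^2 +
                (matrix(1:128, 128, 128) - st$lens_center[2])^2 <= roi$radius^2)
  # analytic mean of the rounded Gaussian spot over the ROI, via the raw plane
  spot_mean <- mean(st$planes[[3]][(matrix(1:128, 128, 128, byrow = TRUE) - 64.5)^2 +
                                     (matrix(1:128, 128, 128) - 64.5)^2 <= roi$radius^2])
  expect_equal(m$focus_ratio, spot_mean / 200, tolerance = 1e-12)
  expect_gt(m$focus_ratio, 1)
})

test_that("transmittance is invariant to global illumination scaling", {
  st <- simulate_focal_stack(transmittance = 0.8, background_grey = 200,
                             noise_sd = 0)
  dimmed <- st
  dimmed$planes <- lapply(st$planes, function(p) p * 0.5)
  expect_equal(measure_stack(dimmed)$transmittance_ratio,
               measure_stack(st)$transmittance_ratio)
})

test_that("group comparison matches the closed-form pooled t-test", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  out <- compare_groups(d, "y", "g")
  expect_equal(out$t, -3.6742346, tolerance = 1e-6)
  expect_equal(out$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(out$df, 4)
  oracle <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, oracle$t, tolerance = 1e-9)
  expect_equal(out$p_value, oracle$p, tolerance = 1e-9)

  set.seed(8)
  for (i in 1:25) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), 0.5)
    d <- tibble::tibble(g = c(rep("a", length(x)), rep("b", length(y))),
                        y = c(x, y))
    out <- compare_groups(d, "y", "g")
    oracle <- oracle_pooled_t(x, y)
    expect_equal(out$t, oracle$t, tolerance = 1e-9)
    expect_equal(out$p_value, oracle$p, tolerance = 1e-9)
    # scale invariance
    d10 <- d; d10$y <- d10$y * 10
    out10 <- compare_groups(d10, "y", "g")
    expect_equal(out10$t, out$t, tolerance = 1e-9)
    expect_equal(out10$p_value, out$p_value, tolerance = 1e-9)
  }

  # identical groups: t = 0, p = 1; fully degenerate: p = 1 convention
  same <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  out <- compare_groups(same, "y", "g")
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  flat <- tibble::tibble(g = rep(c("a", "b"), each = 2), y = rep(5, 4))
  expect_equal(compare_groups(flat, "y", "g")$p_value, 1)
  tiny <- tibble::tibble(g = c("a", "b", "b"), y = 1:3)
  expect_error(compare_groups(tiny, "y", "g"),
               class = "microlens_validation_error")
})

test_that("dose-response summaries order doses and flag only real effects", {
  # all groups identical: every comparison against control gives p = 1
  d <- tibble::tibble(dose = rep(c("0", "200", "2000"), each = 4),
                      transmittance_ratio = rep(c(1, 0.9, 1.1, 1), 3))
  out <- dose_response_summary(d, "transmittance_ratio", "dose", control = "0")
  expect_equal(out$dose, c("0", "200", "2000"))
  expect_true(all(out$p_value == 1))

  # planted monotone-decreasing transmittance gives monotone group means
  set.seed(19)
  meas <- simulate_treatment_groups(
    transmittance_by_dose = c("0" = 0.95, "500" = 0.85, "2000" = 0.75),
    n_per_group = 5, between_lens_sd = 0.01, seed = 19
  )
  out <- dose_response_summary(meas, "transmittance_ratio", "dose", control = "0")
  expect_equal(out$dose, c("0", "500", "2000"))
  expect_true(all(diff(out$mean) < 0))
  expect_true(all(out$p_value[-1] < 0.05))

  expect_error(dose_response_summary(meas, "transmittance_ratio", "dose",
                                     control = "9999"),
               class = "microlens_lookup_error")
})
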