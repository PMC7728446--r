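make_image <- function(n = 101, value = 0) {
  list(DAPI = matrix(1, n, n), M = matrix(value, n, n))
}

test_that("a spatially uniform channel profiles flat", {
  img <- make_image(value = 3.5)
  prof <- radial_profile(img, "M", center = c(50, 50), colony_radius_px = 45)
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$intensity == 3.5))
  expect_false(any(prof$normalized))
})

test_that("a bright annulus at 0.8R peaks in the ring containing 0.8R", {
  n <- 201; ctr <- 100; R <- 90
  grid <- expand.grid(y = 0:(n - 1), x = 0:(n - 1))
  r <- sqrt((grid$x - ctr)^2 + (grid$y - ctr)^2)
  m <- matrix(as.numeric(abs(r - 0.8 * R) < 2), n, n)
  prof <- radial_profile(list(DAPI = matrix(1, n, n), M = m), "M",
                         center = c(ctr, ctr), colony_radius_px = R)
  expect_equal(prof$bin[which.max(prof$intensity)], 16)  # 0.8 * 20
})

test_that("the profile is invariant to 90-degree image rotation", {
  set.seed(1)
  n <- 101
  m <- matrix(runif(n * n), n, n)
  sym <- (m + t(m)) / 2               # any image; rotate and re-profile
  rot <- t(sym)[, n:1]                 # 90-degree rotation
  ctr <- (n - 1) / 2
  p1 <- radial_profile(list(DAPI = matrix(1, n, n), M = sym), "M",
                       center = c(ctr, ctr), colony_radius_px = 45)
  p2 <- radial_profile(list(DAPI = matrix(1, n, n), M = rot), "M",
                       center = c(ctr, ctr), colony_radius_px = 45)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("a ring too narrow for the pixel grid raises a named error", {
  img <- make_image(n = 21)
  expect_error(
    radial_profile(img, "M", center = c(10, 10), colony_radius_px = 2,
                   n_rings = 20),
    "contains no pixels")
})

test_that("circle-sampling mode also profiles a uniform field flat", {
  img <- make_image(value = 2)
  prof <- radial_profile(img, "M", center = c(50, 50), colony_radius_px = 40,
                         method = "circle")
  expect_true(all(prof$intensity == 2))
})

test_that("DAPI normalization computes pointwise ratios with guards", {
  img <- make_image(value = 4)
  marker <- radial_profile(img, "M", center = c(50, 50), colony_radius_px = 45)
  dapi <- radial_profile(img, "DAPI", center = c(50, 50), colony_radius_px = 45)

  identity_case <- normalize_to_dapi(dapi, dapi, epsilon = 0)
  expect_true(all(identity_case$intensity == 1))
  expect_true(all(identity_case$normalized))

  const_case <- normalize_to_dapi(marker, dapi, epsilon = 0)
  expect_true(all(const_case$intensity == 4))

  zero_dapi <- dapi; zero_dapi$intensity[5] <- 0
  expect_error(normalize_to_dapi(marker, zero_dapi, epsilon = 0), "ring")
  guarded <- normalize_to_dapi(marker, zero_dapi, epsilon = 1e-6)
  expect_true(all(is.finite(guarded$intensity)))

  short <- dapi[1:10, ]
  expect_error(normalize_to_dapi(marker, short), "radii")
})

test_that("profile averaging returns per-ring mean and SEM", {
  img <- make_image(value = 1)
  base <- radial_profile(img, "M", center = c(50, 50), colony_radius_px = 45)
  p1 <- base; p1$intensity <- rep(1, 20)
  p3 <- base; p3$intensity <- rep(3, 20)

  avg <- average_profiles(list(p1, p3))
  expect_true(all(avg$mean_intensity == 2))
  expect_equal(avg$sem, rep(1, 20))   # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_equal(avg$n[1], 2)

  expect_warning(one <- average_profiles(list(p1)), "SEM")
  expect_equal(one$mean_intensity, p1$intensity)
  expect_true(all(one$sem == 0))

  same <- average_profiles(list(p3, p3, p3, p3))
  expect_true(all(same$sem == 0))

  expect_error(average_profiles(list()), "nonempty")
})

test_that("the colony center is recovered from the DAPI mask", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 120, T = 0, SOX17 = 0, CDX2 = 120),
                      seed = 14)
  col <- simulate_colony(spec)
  ctr <- find_colony_center(col)
  true_ctr <- (nrow(col$channels$DAPI) - 1) / 2
  expect_lt(abs(ctr["x"] - true_ctr), 12)
  expect_lt(abs(ctr["y"] - true_ctr), 12)
})
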