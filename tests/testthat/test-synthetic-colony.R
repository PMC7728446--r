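test_that("an all-zero cell spec yields pure background and no centroids", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 0, T = 0, SOX17 = 0, CDX2 = 0),
                      background_noise_sd = 0.01, seed = 1)
  col <- simulate_colony(spec)
  expect_equal(nrow(col$centroids), 0)
  # background noise is clipped at zero and small
  expect_true(all(col$channels$DAPI >= 0))
  expect_lt(max(col$channels$DAPI), 0.1)
})

test_that("colony generation is bit-identical for a fixed seed", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 30, T = 20, SOX17 = 10, CDX2 = 15),
                      seed = 42)
  a <- simulate_colony(spec)
  b <- simulate_colony(spec)
  expect_identical(a$channels, b$channels)
  expect_identical(a$centroids, b$centroids)
})

test_that("ring ordering puts every CDX2 centroid outside every SOX2 centroid", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 50, T = 0, SOX17 = 0, CDX2 = 50),
                      seed = 3)
  col <- simulate_colony(spec)
  ctr <- (nrow(col$channels$DAPI) - 1) / 2
  r <- sqrt((col$centroids$x_px - ctr)^2 + (col$centroids$y_px - ctr)^2)
  expect_gt(min(r[col$centroids$marker == "CDX2"]),
            max(r[col$centroids$marker == "SOX2"]))
  # all centroids inside the disc
  radius_px <- spec$diameter_um / (2 * spec$pixel_size_um)
  expect_true(all(r <= radius_px + 1e-9))
})

test_that("a 200-centroid colony yields a density map of mass 200", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 80, T = 50, SOX17 = 30, CDX2 = 40),
                      seed = 5)
  col <- simulate_colony(spec)
  expect_equal(length(unique(col$centroids$cell_id)), 200)
  dm <- density_from_centroids(col, marker = NULL, kernel_sigma_px = 6)
  expect_equal(cell_count(dm), 200, tolerance = 1e-9)
})

test_that("coexpressing cells are one centroid listed under both markers", {
  spec <- colony_spec(
    ring_layout = list(SOX17 = c(0.5, 0.8), T = c(0.3, 0.6)),
    cells_per_marker = c(SOX17 = 40, T = 40),
    coexpression_rules = c("SOX17:T" = 1),  # every possible pair co-expresses
    seed = 8)
  col <- simulate_colony(spec)
  n_cells <- length(unique(col$centroids$cell_id))
  # with probability 1 all min(40, 40) cells are shared: 40 centroids total
  expect_equal(n_cells, 40)
  per_cell <- table(col$centroids$cell_id)
  expect_true(all(per_cell == 2))
  # the same coordinates under both markers
  co <- split(col$centroids, col$centroids$cell_id)[[1]]
  expect_equal(co$x_px[1], co$x_px[2])
})

test_that("impossible ring fractions are rejected", {
  expect_error(colony_spec(ring_layout = list(SOX2 = c(0.5, 0.4)),
                           cells_per_marker = c(SOX2 = 5)),
               "impossible")
  expect_error(colony_spec(ring_layout = list(SOX2 = c(-0.1, 0.4)),
                           cells_per_marker = c(SOX2 = 5)),
               "impossible")
  expect_error(colony_spec(ring_layout = list(SOX2 = c(0.2, 1.4)),
                           cells_per_marker = c(SOX2 = 5)),
               "impossible")
})

test_that("marker channels light up at their centroids", {
  spec <- colony_spec(cells_per_marker = c(SOX2 = 10, T = 0, SOX17 = 0, CDX2 = 0),
                      background_noise_sd = 0, seed = 2)
  col <- simulate_colony(spec)
  cen <- col$centroids[col$centroids$marker == "SOX2", ]
  for (i in seq_len(nrow(cen))) {
    v <- col$channels$SOX2[round(cen$y_px[i]) + 1, round(cen$x_px[i]) + 1]
    expect_gt(v, 0.5)
  }
})

test_that("sorting layouts emit the requested counts and respect mode geometry", {
  tiny <- simulate_sorting_layout(1, 1, mode = "sorted", seed = 1)
  expect_equal(nrow(tiny$centroids), 2)

  srt <- simulate_sorting_layout(150, 150, mode = "sorted", seed = 4)
  ctr <- (nrow(srt$channels$DAPI) - 1) / 2
  xa <- srt$centroids$x_px[srt$centroids$marker == "A"]
  xb <- srt$centroids$x_px[srt$centroids$marker == "B"]
  expect_true(all(xa >= ctr))   # disjoint half-discs
  expect_true(all(xb <= ctr))

  mix <- simulate_sorting_layout(150, 150, mode = "mixed", seed = 4)
  # mixed populations span both halves
  expect_gt(sum(mix$centroids$x_px[mix$centroids$marker == "A"] < ctr), 0)
  expect_gt(sum(mix$centroids$x_px[mix$centroids$marker == "A"] > ctr), 0)
})
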