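test_that("mean displacement matches closed forms", {
  z <- matrix(0, 4, 5)
  expect_equal(mean_displacement(flow_field(z, z)), 0)
  expect_equal(mean_displacement(flow_field(z + 3, z + 4)), 5)
  # half the pixels (1, 0), half (0, 0) -> 0.5
  u <- matrix(c(1, 0), 4, 4)
  expect_equal(mean_displacement(flow_field(u, u * 0)), 0.5)
})

test_that("mean displacement is permutation-invariant and scales linearly", {
  set.seed(1)
  u <- matrix(rnorm(48), 6, 8); v <- matrix(rnorm(48), 6, 8)
  f <- flow_field(u, v)
  perm <- sample(48)
  fp <- flow_field(matrix(u[perm], 6, 8), matrix(v[perm], 6, 8))
  expect_equal(mean_displacement(f), mean_displacement(fp))
  for (c in c(-2.5, 0.5, 3)) {
    expect_equal(mean_displacement(flow_field(c * u, c * v)),
                 abs(c) * mean_displacement(f), tolerance = 1e-12)
  }
})

test_that("segment activity sums frame activities and rejects bad input", {
  expect_equal(segment_activity(rep(1, 600)), 600)
  expect_equal(segment_activity(2.5), 2.5)
  expect_equal(segment_activity(c(1, 2, 3)), 6)
  expect_error(segment_activity(numeric(0)), "non-empty")
  expect_error(segment_activity(c(1, -0.1)), "negative")
})

test_that("normalization maps the reference range onto [0, 100]", {
  expect_equal(normalize_series(c(0, 5, 10)), c(0, 50, 100))
  expect_equal(normalize_series(3, ref_min = 3, ref_max = 9), 0)
  expect_equal(normalize_series(9, ref_min = 3, ref_max = 9), 100)
  # out-of-range values clip
  expect_equal(normalize_series(c(-5, 20), ref_min = 0, ref_max = 10),
               c(0, 100))
  expect_error(normalize_series(c(1, 1), ref_min = 1, ref_max = 1),
               class = "farrowcast_degenerate_range")
  expect_equal(normalize_series(c(1, 1), ref_min = 1, ref_max = 1,
                                allow_constant = TRUE), c(0, 0))
})

test_that("normalize then un-normalize recovers the input", {
  set.seed(2)
  x <- runif(50, 10, 40)
  z <- normalize_series(x, ref_min = 5, ref_max = 45)
  back <- z / 100 * (45 - 5) + 5
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("moving-average smoothing truncates at the edges", {
  expect_equal(smooth_series(c(4, 7, 1), window = 1), c(4, 7, 1))
  expect_equal(smooth_series(rep(3, 10), window = 5), rep(3, 10))
  expect_equal(smooth_series(c(0, 3, 0), window = 3), c(1.5, 1, 1.5))
  expect_error(smooth_series(1:10, window = 4), "odd")
  expect_error(smooth_series(1:3, window = 5), "length")
})

test_that("EPE matches a brute-force per-pixel loop", {
  z <- matrix(0, 3, 3)
  expect_equal(epe(flow_field(z, z), flow_field(z, z)), 0)
  expect_equal(epe(flow_field(z + 3, z + 4), flow_field(z, z)), 5)

  set.seed(3)
  mk <- function() flow_field(matrix(rnorm(256), 16), matrix(rnorm(256), 16))
  pred <- mk(); truth <- mk()
  acc <- 0
  for (i in 1:16) for (j in 1:16) {
    acc <- acc + sqrt((pred$u[i, j] - truth$u[i, j])^2 +
                        (pred$v[i, j] - truth$v[i, j])^2)
  }
  expect_equal(epe(pred, truth), acc / 256, tolerance = 1e-12)
  expect_equal(epe(pred, truth), epe(truth, pred))
  expect_error(epe(pred, flow_field(matrix(0, 4, 4), matrix(0, 4, 4))),
               "dimensions")
})

test_that("Fl-all matches a counting oracle and is monotone in delta", {
  z <- matrix(0, 4, 4)
  f0 <- flow_field(z, z)
  expect_equal(fl_all(f0, f0, delta = 1), 0)
  expect_equal(fl_all(flow_field(z + 3, z + 4), f0, delta = 3), 100)
  u <- matrix(c(5, 0), 4, 4)  # half the pixels error 5, half 0
  expect_equal(fl_all(flow_field(u, u * 0), f0, delta = 3), 50)

  set.seed(4)
  pred <- flow_field(matrix(rnorm(256, sd = 3), 16), matrix(rnorm(256, sd = 3), 16))
  truth <- flow_field(matrix(rnorm(256, sd = 3), 16), matrix(rnorm(256, sd = 3), 16))
  for (delta in c(0.5, 2, 5)) {
    cnt <- 0
    for (i in 1:16) for (j in 1:16) {
      e <- sqrt((pred$u[i, j] - truth$u[i, j])^2 +
                  (pred$v[i, j] - truth$v[i, j])^2)
      if (e > delta) cnt <- cnt + 1
    }
    expect_equal(fl_all(pred, truth, delta), 100 * cnt / 256)
  }
  deltas <- seq(0.1, 8, by = 0.5)
  vals <- vapply(deltas, function(d) fl_all(pred, truth, d), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that(".flo files round-trip through the Middlebury layout", {
  set.seed(5)
  f <- flow_field(matrix(rnorm(35), 5, 7), matrix(rnorm(35), 5, 7))
  path <- withr::local_tempfile(fileext = ".flo")
  write_flo(f, path)
  # header: float magic + int width + int height, then 2*w*h float32
  expect_equal(file.info(path)$size, 12 + 8 * 5 * 7)
  back <- read_flo(path)
  expect_equal(dim(back), c(5L, 7L))
  expect_equal(back$u, f$u, tolerance = 1e-6)  # float32 precision
  expect_equal(back$v, f$v, tolerance = 1e-6)
  # integer-valued fields survive exactly
  g <- flow_field(matrix(3, 4, 4), matrix(-2, 4, 4))
  write_flo(g, path)
  expect_identical(read_flo(path)$u, g$u)
  expect_error({
    writeBin(1:10, path)
    read_flo(path)
  }, "magic")
})

test_that("block matching recovers an integer translation on interior blocks", {
  fp <- generate_flow_pair(32, 32, c(2, 1), seed = 6)
  est <- estimate_flow(fp$frame_a, fp$frame_b, "block_matching",
                       block_size = 8, search_radius = 3)
  interior <- 1:24  # blocks whose true match stays inside the frame
  expect_true(all(est$u[interior, interior] == 2))
  expect_true(all(est$v[interior, interior] == 1))

  same <- estimate_flow(fp$frame_a, fp$frame_a, "block_matching",
                        block_size = 8, search_radius = 2)
  expect_equal(mean_displacement(same), 0)

  expect_error(estimate_flow(fp$frame_a, fp$frame_b, "nonexistent"),
               "block_matching", class = "farrowcast_backend_error")
})

test_that("custom flow backends can be registered", {
  register_flow_backend("constant_zero", function(a, b, ...) {
    flow_field(matrix(0, nrow(a), ncol(a)), matrix(0, nrow(a), ncol(a)))
  })
  f <- estimate_flow(matrix(1, 8, 8), matrix(1, 8, 8), "constant_zero")
  expect_equal(mean_displacement(f), 0)
})

test_that("segment activity composes with per-frame mean displacement", {
  z <- matrix(0, 4, 4)
  fields <- list(flow_field(z + 3, z + 4), flow_field(z, z),
                 flow_field(z + 1, z))
  expect_equal(segment_activity_from_fields(fields), 5 + 0 + 1)
})
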