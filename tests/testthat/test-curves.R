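test_that("curve evaluation interpolates control points and is deterministic", {
  fc <- function_curve(c(0, 0.5, 1), c(0, 0.2, 1))
  # linear two-point case
  lin <- function_curve(c(0, 1), c(0, 1))
  expect_equal(eval_curve(lin, 0.5), 0.5)
  # control points reproduced exactly
  expect_identical(eval_curve(fc, c(0, 0.5, 1)), c(0, 0.2, 1))
  # bit-identical repeated evaluation
  u <- seq(0, 1, length.out = 37)
  expect_identical(eval_curve(fc, u), eval_curve(fc, u))
  # clamping outside [0,1]
  expect_identical(eval_curve(fc, -2), eval_curve(fc, 0))
  expect_identical(eval_curve(fc, 5), eval_curve(fc, 1))
})

test_that("curve evaluation matches an independent monotone-cubic oracle", {
  u <- c(0, 0.5, 1); v <- c(0, 0.2, 1)
  fc <- function_curve(u, v)
  grid <- seq(0, 1, length.out = 1e4)
  expect_equal(eval_curve(fc, grid), fc_oracle(u, v, grid), tolerance = 1e-12)
  expect_equal(eval_curve(fc, 0.25), fc_oracle(u, v, 0.25), tolerance = 1e-12)
  # a non-monotone ordinate sequence is still continuous and interpolating
  u2 <- c(0, 0.3, 0.7, 1); v2 <- c(0.1, 0.9, 0.4, 0.6)
  fc2 <- function_curve(u2, v2)
  vals <- eval_curve(fc2, grid)
  expect_identical(eval_curve(fc2, u2), v2)
  expect_lt(max(abs(diff(vals))), 0.002) # continuity at grid spacing 1e-4
})

test_that("monotone interpolation never overshoots between monotone points", {
  fc <- function_curve(c(0, 0.1, 0.9, 1), c(0, 0.05, 0.95, 1))
  vals <- eval_curve(fc, seq(0, 1, length.out = 5001))
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
})

test_that("curve construction rejects invalid control points", {
  expect_error(function_curve(0, 1), "at least 2")
  expect_error(function_curve(c(0, 0.5, 0.5, 1), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(function_curve(c(0.1, 1), c(0, 1)), "start at 0")
})

test_that("leaf length follows x_mult * f_lmax(n_norm) * f_l(t)", {
  fs <- default_fs()
  n <- 7
  expect_equal(leaf_length(fs, n, 0), 0)          # f_l(0) = 0
  expect_equal(leaf_length(fs, n, 1, 1),
               eval_curve(fs$f_lmax, n / fs$max_node))  # f_l(1) = 1
  # monotone non-decreasing over age, per the elongation curve
  tt <- seq(0, 1, by = 0.1)
  lens <- leaf_length(fs, n, tt)
  expect_true(all(diff(lens) >= -1e-12))
  expect_equal(lens, 1 * eval_curve(fs$f_lmax, n / fs$max_node) *
                 eval_curve(fs$f_l, tt))
})

test_that("leaf width is the shape-invariant contour scaled by length", {
  fs <- default_fs()
  expect_equal(leaf_width(fs, 5, 0.8, 0), 0)
  expect_equal(leaf_width(fs, 5, 0.8, 1), 0)
  # doubling x_mult doubles width everywhere
  x <- seq(0, 1, by = 0.05)
  expect_equal(leaf_width(fs, 5, 0.7, x, x_mult = 2),
               2 * leaf_width(fs, 5, 0.7, x, x_mult = 1))
  # width profile at maturity is the contour times the final length
  expect_equal(leaf_width(fs, 5, 1, x),
               2 * eval_curve(fs$f_lmax, 5 / fs$max_node) *
                 eval_curve(fs$f_lw, x))
  # contour ratio independent of age and size multiplier
  r1 <- leaf_width(fs, 5, 0.4, 0.3, 1.1) / leaf_length(fs, 5, 0.4, 1.1)
  r2 <- leaf_width(fs, 5, 0.9, 0.3, 0.9) / leaf_length(fs, 5, 0.9, 0.9)
  expect_equal(r1, r2)
})

test_that("default function set satisfies the model invariants", {
  fs <- default_fs()
  grid <- seq(0, 1, length.out = 1001)
  expect_equal(eval_curve(fs$f_l, 0), 0)
  expect_equal(eval_curve(fs$f_l, 1), 1)
  expect_true(all(diff(eval_curve(fs$f_l, grid)) >= -1e-12))
  expect_equal(eval_curve(fs$f_lw, c(0, 1)), c(0, 0))
  # ovate contour: interior maximum, past the blade middle
  lw <- eval_curve(fs$f_lw, grid)
  amax <- grid[which.max(lw)]
  expect_gt(amax, 0.05); expect_lt(amax, 0.95)
  ang <- eval_curve(fs$f_ang, grid)
  expect_true(all(ang >= 0 & ang <= 90))
  # f_lmax rises to a mid-rosette maximum then declines
  lmax <- eval_curve(fs$f_lmax, grid)
  apos <- grid[which.max(lmax)]
  expect_gt(apos, 0.1); expect_lt(apos, 0.9)
  expect_lt(lmax[1], max(lmax))
  expect_lt(lmax[length(lmax)], max(lmax))
})

test_that("function sets round-trip through serialization unchanged", {
  fs <- default_fs()
  path <- tempfile(fileext = ".yaml")
  save_function_set(fs, path)
  fs2 <- load_function_set(path)
  for (nm in c("f_lmax", "f_l", "f_lw", "f_ang")) {
    expect_identical(fs[[nm]]$u, fs2[[nm]]$u)
    expect_identical(fs[[nm]]$v, fs2[[nm]]$v)
  }
  expect_identical(fs$petiole_length_fraction, fs2$petiole_length_fraction)
  expect_identical(fs$petiole_width, fs2$petiole_width)
  grid <- seq(0, 1, length.out = 100)
  expect_identical(eval_curve(fs$f_lmax, grid), eval_curve(fs2$f_lmax, grid))
})
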