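# a minimal scene: one horizontal mature blade lying along +x
flat_blade_scene <- function(fs, length = 1, n = 10) {
  s <- lstring(list(lmod("&", 90), lmod("L", n, 1e9, length)))
  interpret(s, fs)
}

test_that("projected diameter of simple scenes is analytic", {
  fs <- default_fs()
  # a single horizontal blade of length l projects to extent ~ l * x_mult
  xm <- 1 / eval_curve(fs$f_lmax, 10 / fs$max_node) # normalize to length 1
  sc <- flat_blade_scene(fs, length = xm)
  expect_equal(compute_diameter(sc, fs), 1, tolerance = 0.01)
  # two opposite blades of projected radius r give diameter 2r
  s2 <- lstring(list(
    lmod("["), lmod("&", 90), lmod("L", 10, 1e9, xm), lmod("]"),
    lmod("/", 180), lmod("&", 90), lmod("L", 10, 1e9, xm)))
  sc2 <- interpret(s2, fs)
  expect_equal(compute_diameter(sc2, fs), 2, tolerance = 0.02)
})

test_that("projected diameter is invariant under rotation about vertical", {
  fs <- default_fs()
  p <- sample_rosette_params(seed = 41)
  plant <- build_rosette(p, fs)
  d0 <- compute_diameter(plant$scene, fs)
  for (rot in c(30, 45, 137.5)) {
    rotated <- interpret(
      lstring(c(list(lmod("/", rot)), unclass(plant$string))), fs)
    expect_equal(compute_diameter(rotated, fs), d0, tolerance = 0.01 * d0)
  }
  expect_error(compute_diameter(structure(list(primitives = list()),
                                          class = "scene"), fs),
               "empty scene")
})

test_that("soil background pixels equal the flat background color exactly", {
  fs <- default_fs()
  sc <- flat_blade_scene(fs, 0.1)
  cfg <- render_config(image_size = 64, background_mode = "soil")
  smp <- render(sc, cfg, fs, seed = 3)
  expect_gte(sum(smp$mask), 1)
  for (ch in 1:3) {
    plane <- smp$image[, , ch]
    expect_true(all(plane[!smp$mask] == cfg$soil_color[ch]))
  }
  # and every foreground pixel differs from the background color
  fg_differs <- rep(FALSE, sum(smp$mask))
  for (ch in 1:3)
    fg_differs <- fg_differs |
      (smp$image[, , ch][smp$mask] != cfg$soil_color[ch])
  expect_true(all(fg_differs))
})

test_that("black background mode zeroes all non-mask pixels", {
  fs <- default_fs()
  p <- sample_rosette_params(seed = 42)
  plant <- build_rosette(p, fs)
  smp <- render(plant$scene, render_config(image_size = 48,
                                           background_mode = "black"),
                fs, seed = 5)
  for (ch in 1:3)
    expect_true(all(smp$image[, , ch][!smp$mask] == 0))
})

test_that("realized mask diameter tracks the drawn scale ratio", {
  fs <- default_fs()
  p <- sample_rosette_params(stochastic_config(leaf_count_range = c(10, 14)),
                             seed = 43)
  plant <- build_rosette(p, fs)
  S <- 96
  smp <- render(plant$scene, render_config(image_size = S), fs, seed = 11)
  px <- which(smp$mask, arr.ind = TRUE)
  hull <- grDevices::chull(px)
  d_mask <- max(stats::dist(px[hull, ]))
  expect_lt(abs(d_mask - smp$scale_ratio * S), 2.5)
})

test_that("rendering is deterministic: identical seeds, identical PNG bytes", {
  fs <- default_fs()
  p <- sample_rosette_params(seed = 44)
  plant <- build_rosette(p, fs)
  cfg <- render_config(image_size = 48, background_mode = "mixed")
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_sample_png(render(plant$scene, cfg, fs, seed = 123), f1)
  write_sample_png(render(plant$scene, cfg, fs, seed = 123), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  f3 <- tempfile(fileext = ".png")
  write_sample_png(render(plant$scene, cfg, fs, seed = 124), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("mixed backgrounds follow the configured probability", {
  fs <- default_fs()
  sc <- flat_blade_scene(fs, 0.5)
  cfg <- render_config(image_size = 32, background_mode = "mixed",
                       mixed_p = 0.5)
  kinds <- vapply(1:400, function(i)
    render(sc, cfg, fs, seed = 9000 + i)$background_kind, character(1))
  frac <- mean(kinds == "random_rgb")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("apply_mask_black keeps foreground and zeroes background", {
  img <- array(0.5, c(8, 8, 3))
  expect_identical(apply_mask_black(img, matrix(1, 8, 8)), img)
  expect_identical(apply_mask_black(img, matrix(0, 8, 8)),
                   array(0, c(8, 8, 3)))
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  out <- apply_mask_black(img, checker)
  expect_identical(sum(out[, , 1] == 0), 32L)
  expect_identical(sum(out[, , 1] == 0.5), 32L)
  expect_error(apply_mask_black(img, matrix(1, 4, 4)), "dimensions")
})

test_that("sample PNG round trip preserves image and mask", {
  fs <- default_fs()
  p <- sample_rosette_params(seed = 45)
  plant <- build_rosette(p, fs)
  smp <- render(plant$scene, render_config(image_size = 48), fs, seed = 6)
  fi <- tempfile(fileext = ".png"); fm <- tempfile(fileext = ".png")
  write_sample_png(smp, fi, fm)
  img <- read_image_png(fi)
  expect_equal(dim(img), c(48, 48, 3))
  expect_lt(max(abs(img - smp$image)), 1 / 255) # 8-bit quantization only
  expect_identical(read_mask_png(fm), matrix(as.logical(smp$mask), 48, 48))
})
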