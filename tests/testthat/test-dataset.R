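test_that("a minimal generation run writes image, mask, labels and spec", {
  dir <- tempfile()
  spec <- dataset_spec("mini", 1, c(6, 8), image_size = 32, master_seed = 2)
  man <- generate_dataset(spec, dir, blade_res = c(8, 3))
  expect_identical(nrow(man$records), 1L)
  expect_true(file.exists(file.path(dir, man$records$filename)))
  expect_true(file.exists(file.path(dir, man$records$mask)))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_identical(names(labs), c("filename", "leaf_count"))
  expect_true(all(labs$leaf_count >= 6 & labs$leaf_count <= 8))
})

test_that("loading a generated dataset reproduces every (filename, count)", {
  man <- small_s12()
  loaded <- load_dataset(man$dir)
  expect_identical(loaded$records$filename, man$records$filename)
  expect_identical(loaded$records$leaf_count, man$records$leaf_count)
  expect_identical(loaded$records$mask, man$records$mask)
  expect_identical(loaded$spec$name, "S12")
})

test_that("generation is bit-identical under the same spec", {
  n <- 100
  spec <- dataset_spec("det", n, c(5, 9), image_size = 32, master_seed = 31)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_dataset(spec, d1, blade_res = c(8, 3))
  m2 <- generate_dataset(spec, d2, blade_res = c(8, 3))
  for (f in m1$records$filename[c(1, 25, 50, 100)]) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  # a different master seed shares no identical image bytes (100 pairs)
  spec3 <- dataset_spec("det", n, c(5, 9), image_size = 32, master_seed = 32)
  d3 <- tempfile()
  m3 <- generate_dataset(spec3, d3, blade_res = c(8, 3))
  same <- vapply(seq_len(n), function(i) {
    f1 <- file.path(d1, m1$records$filename[i])
    f3 <- file.path(d3, m3$records$filename[i])
    identical(readBin(f1, "raw", file.size(f1)),
              readBin(f3, "raw", file.size(f3)))
  }, logical(1))
  expect_false(any(same))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("labels equal the blade count of the regenerated scene", {
  man <- small_s12()
  scfg <- stochastic_config(leaf_count_range = man$spec$leaf_count_range)
  for (i in c(1, 7, 24)) {
    # replay the recorded per-sample seed chain
    sample_seed <- man$records$seed[i]
    rebuilt <- NULL
    for (attempt in 1:25) {
      pseed <- derive_seed(sample_seed, attempt)
      params <- sample_rosette_params(scfg, seed = pseed)
      plant <- build_rosette(params)
      smp <- render(plant$scene,
                    render_config(image_size = man$spec$image_size,
                                  background_mode = man$spec$background_mode,
                                  blade_res = c(12, 4)),
                    seed = derive_seed(pseed, 1L))
      if (smp$all_blades_visible) { rebuilt <- plant; break }
    }
    expect_identical(man$records$leaf_count[i],
                     scene_count(rebuilt$scene, "blade"))
  }
})

test_that("label-only S12 runs are uniform over 5..20", {
  for (seed in c(1, 2, 3)) {
    spec <- dataset_preset("S12", master_seed = seed)
    man <- generate_dataset(spec, tempfile(), render = FALSE)
    labs <- man$records$leaf_count
    expect_identical(nrow(man$records), 1000L)
    expect_true(all(labs >= 5 & labs <= 20))
    chi <- suppressWarnings(chisq.test(table(factor(labs, levels = 5:20))))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("PRL-style directories load, with masks and headerless CSV", {
  dir <- tempfile(); dir.create(dir)
  set.seed(61)
  for (i in 1:3) {
    img <- array(runif(16 * 16 * 3), c(16, 16, 3))
    png::writePNG(img, file.path(dir, sprintf("plant%03d_rgb.png", i)))
    png::writePNG(matrix(1, 16, 16),
                  file.path(dir, sprintf("plant%03d_rgb_label.png", i)))
  }
  writeLines(c("plant001_rgb.png,5", "plant002_rgb.png,7",
               "plant003_rgb.png,12"), file.path(dir, "counts.csv"))
  man <- load_dataset(dir)
  expect_identical(man$records$filename,
                   sprintf("plant%03d_rgb.png", 1:3))
  expect_identical(man$records$leaf_count, c(5L, 7L, 12L))
  expect_identical(man$records$mask,
                   sprintf("plant%03d_rgb_label.png", 1:3))
})

test_that("label CSV validation names the offending line", {
  dir <- tempfile(); dir.create(dir)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "a.png"))
  writeLines(c("filename,leaf_count", "a.png,abc"),
             file.path(dir, "labels.csv"))
  expect_error(load_dataset(dir), "line 2")
  writeLines(c("filename,leaf_count", "missing.png,4"),
             file.path(dir, "labels.csv"))
  expect_error(load_dataset(dir), "missing image")
})

test_that("train/test split is disjoint, exhaustive and reproducible", {
  fake <- structure(list(
    spec = NULL, dir = ".",
    records = data.frame(filename = sprintf("f%04d.png", 1:1000),
                         leaf_count = rep(5:20, length.out = 1000))),
    class = "dataset_manifest")
  sp <- split_train_test(fake, 0.8, seed = 7)
  expect_identical(nrow(sp$train$records), 800L)
  expect_identical(nrow(sp$test$records), 200L)
  expect_length(intersect(sp$train$records$filename,
                          sp$test$records$filename), 0)
  expect_setequal(c(sp$train$records$filename, sp$test$records$filename),
                  fake$records$filename)
  sp2 <- split_train_test(fake, 0.8, seed = 7)
  expect_identical(sp$train$records$filename, sp2$train$records$filename)
  # floor rule: 5 records at 0.8 -> 4 train / 1 test
  tiny <- fake; tiny$records <- fake$records[1:5, ]
  sp3 <- split_train_test(tiny, 0.8, seed = 1)
  expect_identical(nrow(sp3$train$records), 4L)
  expect_identical(nrow(sp3$test$records), 1L)
})
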