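tiny_cfg <- function(...) {
  counter_config("small", input_size = 20, filters = c(2, 3), epochs = 5,
                 batch_size = 4, seed = 3, ...)
}

test_that("both architectures emit one scalar per image and handle zeros", {
  set.seed(1)
  for (arch in c("small", "large")) {
    side <- if (arch == "small") 48 else 96
    cfg <- counter_config(arch, input_size = side, filters = if (arch == "small")
      c(4, 6, 6) else c(4, 6, 6, 8), fc_units = 32, seed = 1)
    m <- build_counter(cfg)
    x <- list(array(runif(side * side * 3), c(side, side, 3)),
              array(0, c(side, side, 3)))
    preds <- predict(m, x)
    expect_length(preds, 2)
    expect_true(all(is.finite(preds)))
  }
  expect_error(counter_config("tiny"), "arg")
  expect_error(build_counter(counter_config("small", input_size = 16)),
               "too small")
})

test_that("fully connected parameter count matches the layer arithmetic", {
  cfg <- counter_config("large", input_size = 96, filters = c(4, 6, 6, 8),
                        fc_units = 32, seed = 2)
  m <- build_counter(cfg)
  flat <- m$dims$flat
  h <- 96
  for (l in 1:4) {
    h <- h - 5 + 1          # 5x5 convolution, stride 1, valid
    h <- (h - 3) %/% 2 + 1  # 3x3 pooling, stride 2
  }
  expect_equal(flat, h * h * 8)
  expect_equal(length(m$weights$fc_W) + length(m$weights$fc_b),
               flat * 32 + 32)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  m <- build_counter(cfg)
  set.seed(8)
  xs <- lapply(1:3, function(i) array(runif(20 * 20 * 3) - 0.5, c(20, 20, 3)))
  y <- c(5, 9, 12)
  g <- rosettesim:::counter_batch(m, xs, y, want_grad = TRUE)
  loss_at <- function(model) {
    p <- rosettesim:::counter_batch(model, xs, want_grad = FALSE)$preds
    mean((p - y)^2)
  }
  eps <- 1e-5
  check_slot <- function(get, set, analytic, k = 6) {
    set.seed(k)
    idx <- sample(length(get(m)), min(k, length(get(m))))
    for (i in idx) {
      mp <- m; wp <- get(mp); wp[i] <- wp[i] + eps; mp <- set(mp, wp)
      mm <- m; wm <- get(mm); wm[i] <- wm[i] - eps; mm <- set(mm, wm)
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-4)
    }
  }
  for (l in 1:2) {
    check_slot(function(mo) mo$weights$conv_W[[l]],
               function(mo, w) { mo$weights$conv_W[[l]] <- w; mo },
               g$d_conv_W[[l]])
    check_slot(function(mo) mo$weights$conv_b[[l]],
               function(mo, w) { mo$weights$conv_b[[l]] <- w; mo },
               g$d_conv_b[[l]])
  }
  check_slot(function(mo) mo$weights$out_W,
             function(mo, w) { mo$weights$out_W <- w; mo },
             g$d_out_W)
  mb <- m; mb$weights$out_b <- m$weights$out_b + eps
  mc <- m; mc$weights$out_b <- m$weights$out_b - eps
  expect_equal(g$d_out_b, (loss_at(mb) - loss_at(mc)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("analytic gradients match finite differences through the fc layer", {
  cfg <- counter_config("large", input_size = 26, filters = c(2, 2),
                        fc_units = 5, seed = 4)
  m <- build_counter(cfg)
  set.seed(9)
  xs <- list(array(runif(26 * 26 * 3) - 0.5, c(26, 26, 3)))
  y <- 7
  g <- rosettesim:::counter_batch(m, xs, y, want_grad = TRUE)
  loss_at <- function(model)
    (rosettesim:::counter_batch(model, xs, want_grad = FALSE)$preds - y)^2
  eps <- 1e-5
  set.seed(10)
  for (i in sample(length(m$weights$fc_W), 6)) {
    mp <- m; mp$weights$fc_W[i] <- mp$weights$fc_W[i] + eps
    mm <- m; mm$weights$fc_W[i] <- mm$weights$fc_W[i] - eps
    expect_equal(g$d_fc_W[i], (loss_at(mp) - loss_at(mm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("augmentations are identity when disabled and involutive flips", {
  set.seed(12)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  out <- augment_image(img, flips = FALSE, crop = FALSE, brightness = FALSE,
                       contrast = FALSE)
  expect_identical(out, img)
  # a forced double horizontal flip restores the original
  flipped <- img[, 24:1, , drop = FALSE]
  expect_identical(flipped[, 24:1, , drop = FALSE], img)
  # augmented output keeps dimensions and stays in [0, 1]
  for (i in 1:50) {
    a <- augment_image(img)
    expect_identical(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("crop windows always lie fully inside the image", {
  H <- 37
  set.seed(13)
  for (i in 1:10000) {
    ch <- as.integer(round(0.9 * H))
    oy <- sample.int(H - ch + 1L, 1L) - 1L
    expect_true(oy >= 0 && oy + ch <= H)
  }
  # and augment_image itself never produces NA from out-of-bounds reads
  img <- array(runif(H * H * 3), c(H, H, 3))
  for (i in 1:50)
    expect_false(anyNA(augment_image(img, flips = FALSE, brightness = FALSE,
                                     contrast = FALSE)))
})

test_that("metric identities hold on fuzzed prediction vectors", {
  set.seed(14)
  for (i in 1:10000) {
    n <- sample(2:12, 1)
    truths <- sample(0:20, n, replace = TRUE)
    preds <- truths + rnorm(n, 0, sample(c(0.1, 1, 5), 1))
    m <- eval_metrics(preds, truths)
    expect_gte(m$abs_count_diff_mean, abs(m$count_diff_mean))
    expect_gte(m$mse, m$count_diff_mean^2)
    expect_gte(m$agreement_pct, 0)
    expect_lte(m$agreement_pct, 100)
    if (!is.na(m$r_squared)) expect_lte(m$r_squared, 1)
  }
})

test_that("metrics match hand computations, including negative R^2", {
  p <- eval_metrics(c(3, 4, 5), c(3, 4, 5))
  expect_equal(p$abs_count_diff_mean, 0)
  expect_equal(p$mse, 0)
  expect_equal(p$r_squared, 1)
  expect_equal(p$agreement_pct, 100)
  m <- eval_metrics(c(4, 4, 4), c(3, 4, 5))
  expect_equal(m$abs_count_diff_mean, 2 / 3)
  expect_equal(m$count_diff_mean, 0)
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$r_squared, 0) # SS_res = 2, SS_tot = 2
  expect_equal(m$agreement_pct, 100 / 3)
  # a constant predictor worse than the truth mean has negative R^2
  w <- eval_metrics(c(9, 9, 9), c(1, 2, 9))
  expect_equal(w$r_squared, 1 - 113 / ((1 - 4)^2 + (2 - 4)^2 + (9 - 4)^2))
  expect_lt(w$r_squared, -1.9)
  # rounding is half away from zero
  expect_equal(eval_metrics(2.5, 2)$abs_count_diff_mean, 1)
})

test_that("evaluation is invariant to sample order", {
  set.seed(15)
  truths <- sample(5:20, 40, replace = TRUE)
  preds <- truths + rnorm(40)
  ord <- sample(40)
  a <- eval_metrics(preds, truths)
  b <- eval_metrics(preds[ord], truths[ord])
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("a short training run decreases the loss and is reproducible", {
  man <- small_s12()
  dat <- load_images(man, 48)
  cfg <- counter_config("small", input_size = 48, filters = c(4, 8, 8),
                        epochs = 12, batch_size = 8, seed = 21)
  m1 <- train_counter(build_counter(cfg), dat$x, dat$y, augment = FALSE)
  expect_true(all(is.finite(m1$loss_history$train_loss)))
  expect_lt(m1$loss_history$train_loss[12], m1$loss_history$train_loss[1])
  m2 <- train_counter(build_counter(cfg), dat$x, dat$y, augment = FALSE)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(predict(m1, dat$x[1:3]), predict(m2, dat$x[1:3]))
})

test_that("training with augmentation and validation records both losses", {
  man <- small_s12()
  dat <- load_images(man, 48)
  cfg <- counter_config("small", input_size = 48, filters = c(4, 8, 8),
                        epochs = 3, batch_size = 8, seed = 22)
  m <- train_counter(build_counter(cfg), dat$x[1:16], dat$y[1:16],
                     validation = list(x = dat$x[17:24], y = dat$y[17:24]))
  expect_identical(nrow(m$loss_history), 3L)
  expect_true(all(is.finite(m$loss_history$val_loss)))
  expect_s3_class(evaluate_counter(m, dat$x[17:24], dat$y[17:24]),
                  "eval_metrics")
})
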