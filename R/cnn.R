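#' Leaf-counter configuration
#'
#' Hyperparameters of the CNN count regressor. Two architectures are
#' provided: `"small"` (three 5x5 convolution layers, each followed by 3x3
#' max pooling with stride 2, then a linear output) and `"large"` (four
#' convolution/pooling blocks plus a 1024-unit fully connected layer before
#' the linear output). tanh follows every convolution and the fully
#' connected layer. Training minimizes squared count error with L2 weight
#' decay `lambda = 1e-4` at a static learning rate of `1e-3`.
#'
#' @param architecture `"small"` or `"large"`.
#' @param input_size Input image side in pixels (default 256; use smaller
#'   sizes for fast desk-scale runs).
#' @param filters Integer vector of filters per convolution layer; defaults
#'   to `c(32, 64, 64)` (small) or `c(32, 64, 64, 128)` (large).
#' @param kernel Convolution kernel side (default 5, stride 1).
#' @param pool,pool_stride Max-pooling geometry (default 3x3, stride 2).
#' @param fc_units Fully connected units for the large architecture
#'   (default 1024).
#' @param weight_decay L2 penalty lambda (default 1e-4).
#' @param learning_rate Static learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param epochs Training epochs (default 100).
#' @param patience Early-stopping patience on held-out loss (default 20;
#'   only applies when validation data are supplied).
#' @param optimizer `"adam"` (default) or `"sgd"`; the static learning rate
#'   is honored either way.
#' @param augment List of augmentation switches: `flips`, `crop`,
#'   `crop_fraction` (default 0.10), `brightness`, `contrast`.
#' @param split_fraction Train fraction used by experiment drivers
#'   (default 0.8).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `counter_config`.
#' @export
counter_config <- function(architecture = c("small", "large"),
                           input_size = 256, filters = NULL, kernel = 5,
                           pool = 3, pool_stride = 2, fc_units = 1024,
                           weight_decay = 1e-4, learning_rate = 1e-3,
                           batch_size = 16, epochs = 100, patience = 20,
                           optimizer = c("adam", "sgd"),
                           augment = list(flips = TRUE, crop = TRUE,
                                          crop_fraction = 0.10,
                                          brightness = TRUE, contrast = TRUE),
                           split_fraction = 0.8, seed = 1) {
  architecture <- match.arg(architecture)
  optimizer <- match.arg(optimizer)
  if (is.null(filters))
    filters <- if (architecture == "small") c(32L, 64L, 64L)
               else c(32L, 64L, 64L, 128L)
  stopifnot(weight_decay >= 0, learning_rate > 0, batch_size >= 1,
            augment$crop_fraction > 0, augment$crop_fraction < 1)
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), pool_stride = as.integer(pool_stride),
                 fc_units = as.integer(fc_units),
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 optimizer = optimizer, augment = augment,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "counter_config")
}

# spatial sizes after each conv/pool block; errors if a layer underflows
counter_dims <- function(cfg) {
  h <- cfg$input_size
  c_in <- 3L
  out <- list()
  for (l in seq_along(cfg$filters)) {
    hc <- h - cfg$kernel + 1L
    if (hc < cfg$pool)
      stop(sprintf(
        "input size %d is too small for %d conv/pool blocks (layer %d)",
        cfg$input_size, length(cfg$filters), l), call. = FALSE)
    hp <- (hc - cfg$pool) %/% cfg$pool_stride + 1L
    out[[l]] <- list(conv = hc, pool = hp, c_in = c_in,
                     c_out = cfg$filters[l])
    c_in <- cfg$filters[l]
    h <- hp
  }
  list(blocks = out, flat = h * h * c_in)
}

#' Build an (untrained) leaf counter
#'
#' Initializes the network weights (Glorot-uniform, appropriate for tanh)
#' for the configured architecture and returns a `leaf_counter` model
#' object. The object is trained with [train_counter()].
#'
#' @param cfg A [counter_config()].
#' @return An object of class `leaf_counter`.
#' @export
build_counter <- function(cfg = counter_config()) {
  stopifnot(inherits(cfg, "counter_config"))
  set.seed(cfg$seed)
  dims <- counter_dims(cfg)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  conv_W <- list(); conv_b <- list()
  for (l in seq_along(cfg$filters)) {
    b <- dims$blocks[[l]]
    fan_in <- cfg$kernel^2 * b$c_in
    conv_W[[l]] <- glorot(fan_in, b$c_out)
    conv_b[[l]] <- rep(0, b$c_out)
  }
  weights <- list(conv_W = conv_W, conv_b = conv_b)
  if (cfg$architecture == "large") {
    weights$fc_W <- glorot(dims$flat, cfg$fc_units)
    weights$fc_b <- rep(0, cfg$fc_units)
    weights$out_W <- as.numeric(glorot(cfg$fc_units, 1))
  } else {
    weights$fc_W <- NULL
    weights$fc_b <- NULL
    weights$out_W <- as.numeric(glorot(dims$flat, 1))
  }
  weights$out_b <- 0
  structure(list(config = cfg, dims = dims, weights = weights,
                 trained = FALSE, loss_history = NULL),
            class = "leaf_counter")
}

counter_batch <- function(model, xs, y = NULL, want_grad = FALSE) {
  w <- model$weights
  cnn_batch_cpp(w$conv_W, w$conv_b, model$config$kernel, model$config$pool,
                model$config$pool_stride, w$fc_W, w$fc_b, w$out_W, w$out_b,
                xs, if (is.null(y)) numeric(0) else as.numeric(y),
                want_grad)
}

#' Augment a training image
#'
#' The standard augmentations of the training regime: independent 50%
#' vertical and horizontal flips; a crop to a window `1 - crop_fraction` of
#' the linear size at a uniformly random position inside the image, resized
#' back to the input size (bilinear); a random brightness offset (±0.1 of
#' the dynamic range) and contrast factor (in \[0.8, 1.2\], about the
#' mid-gray point). Draws come from R's RNG; the label is untouched.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param flips,crop,brightness,contrast Logical switches.
#' @param crop_fraction Fraction of linear size removed by the crop
#'   (default 0.10).
#' @return The augmented image array (same dimensions).
#' @export
augment_image <- function(img, flips = TRUE, crop = TRUE,
                          crop_fraction = 0.10, brightness = TRUE,
                          contrast = TRUE) {
  d <- dim(img)
  if (flips) {
    if (stats::runif(1) < 0.5) img <- img[d[1]:1, , , drop = FALSE]
    if (stats::runif(1) < 0.5) img <- img[, d[2]:1, , drop = FALSE]
  }
  if (crop) {
    ch <- max(1L, as.integer(round((1 - crop_fraction) * d[1])))
    cw <- max(1L, as.integer(round((1 - crop_fraction) * d[2])))
    oy <- sample.int(d[1] - ch + 1L, 1L) - 1L
    ox <- sample.int(d[2] - cw + 1L, 1L) - 1L
    win <- img[(oy + 1):(oy + ch), (ox + 1):(ox + cw), , drop = FALSE]
    img <- resize_bilinear_cpp(win, d[1], d[2])
  }
  if (brightness) img <- img + stats::runif(1, -0.1, 0.1)
  if (contrast) img <- (img - 0.5) * stats::runif(1, 0.8, 1.2) + 0.5
  pmin(pmax(img, 0), 1)
}

#' Train a leaf counter
#'
#' Mini-batch gradient descent on the mean squared count error plus the L2
#' weight penalty, at the configured static learning rate (Adam by
#' default). Records the training loss (and held-out loss, when validation
#' data are given) per epoch; with a fixed seed and single-threaded BLAS
#' two runs produce identical histories. Early stopping monitors the
#' held-out loss with the configured patience and restores the best
#' weights.
#'
#' @param model A `leaf_counter` from [build_counter()].
#' @param x List of input image arrays (input_size x input_size x 3,
#'   values in \[0, 1\]).
#' @param y Numeric vector of true leaf counts.
#' @param validation Optional list `list(x = ..., y = ...)` of held-out
#'   data for the loss history and early stopping.
#' @param epochs Override of `config$epochs`.
#' @param augment Logical; apply [augment_image()] to each training image
#'   every epoch according to the config switches (default `TRUE`).
#' @param verbose Print per-epoch losses.
#' @return The trained `leaf_counter` (with `$loss_history`).
#' @export
train_counter <- function(model, x, y, validation = NULL, epochs = NULL,
                          augment = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "leaf_counter"), length(x) == length(y),
            length(x) > 0)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  set.seed(cfg$seed + 1L)
  x <- lapply(x, function(im) im - 0.5) # center inputs
  vx <- NULL
  if (!is.null(validation)) {
    vx <- lapply(validation$x, function(im) im - 0.5)
    vy <- validation$y
  }
  w <- model$weights
  # center the output at the label mean so the linear head starts unbiased
  if (!model$trained && identical(w$out_b, 0)) w$out_b <- mean(y)
  # flatten weight list for the optimizer
  wnames <- c(paste0("conv_W", seq_along(w$conv_W)),
              paste0("conv_b", seq_along(w$conv_b)),
              if (!is.null(w$fc_W)) c("fc_W", "fc_b"), "out_W", "out_b")
  getw <- function(nm) {
    if (grepl("^conv_W", nm)) w$conv_W[[as.integer(sub("conv_W", "", nm))]]
    else if (grepl("^conv_b", nm)) w$conv_b[[as.integer(sub("conv_b", "", nm))]]
    else w[[nm]]
  }
  setw <- function(nm, val) {
    if (grepl("^conv_W", nm)) w$conv_W[[as.integer(sub("conv_W", "", nm))]] <<- val
    else if (grepl("^conv_b", nm)) w$conv_b[[as.integer(sub("conv_b", "", nm))]] <<- val
    else w[[nm]] <<- val
  }
  adam_m <- lapply(wnames, function(nm) getw(nm) * 0)
  adam_v <- adam_m
  names(adam_m) <- names(adam_v) <- wnames
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
  n <- length(x)
  hist_rows <- vector("list", epochs)
  best_val <- Inf; best_w <- NULL; stall <- 0L
  grad_of <- function(g, nm) {
    if (grepl("^conv_W", nm)) g$d_conv_W[[as.integer(sub("conv_W", "", nm))]]
    else if (grepl("^conv_b", nm)) g$d_conv_b[[as.integer(sub("conv_b", "", nm))]]
    else g[[paste0("d_", nm)]]
  }
  decay_of <- function(nm) if (grepl("_b", nm) || nm == "out_b") 0
                           else cfg$weight_decay
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[idx]
      if (augment) {
        a <- cfg$augment
        xb <- lapply(xb, function(im)
          augment_image(im + 0.5, flips = isTRUE(a$flips),
                        crop = isTRUE(a$crop),
                        crop_fraction = a$crop_fraction %||% 0.10,
                        brightness = isTRUE(a$brightness),
                        contrast = isTRUE(a$contrast)) - 0.5)
      }
      model$weights <- w
      g <- counter_batch(model, xb, y[idx], want_grad = TRUE)
      if (!is.finite(g$loss))
        stop("non-finite training loss (epoch ", ep, "); aborting",
             call. = FALSE)
      ep_loss <- ep_loss + g$loss; nb <- nb + 1L
      tstep <- tstep + 1
      for (nm in wnames) {
        gr <- grad_of(g, nm) + 2 * decay_of(nm) * getw(nm)
        if (cfg$optimizer == "adam") {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr^2
          mhat <- adam_m[[nm]] / (1 - b1^tstep)
          vhat <- adam_v[[nm]] / (1 - b2^tstep)
          setw(nm, getw(nm) - cfg$learning_rate * mhat / (sqrt(vhat) + eps))
        } else {
          setw(nm, getw(nm) - cfg$learning_rate * gr)
        }
      }
    }
    train_loss <- ep_loss / nb
    val_loss <- NA_real_
    if (!is.null(vx)) {
      model$weights <- w
      vp <- counter_batch(model, vx, vy, want_grad = FALSE)
      val_loss <- mean((vp$preds - vy)^2)
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_w <- w; stall <- 0L
      } else stall <- stall + 1L
    }
    hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = train_loss,
                                  val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    if (!is.null(vx) && stall >= cfg$patience) break
  }
  if (!is.null(best_w)) w <- best_w
  model$weights <- w
  model$trained <- TRUE
  model$loss_history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                         logical(1))])
  model
}

#' Predict leaf counts
#'
#' @param object A trained `leaf_counter`.
#' @param newdata A list of image arrays (or a single array) matching the
#'   model's input size, values in \[0, 1\].
#' @param ... Unused.
#' @return Numeric vector of real-valued count predictions (round them for
#'   integer counts; [evaluate_counter()] does this).
#' @export
predict.leaf_counter <- function(object, newdata, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3) newdata <- list(newdata)
  xs <- lapply(newdata, function(im) im - 0.5)
  out <- numeric(length(xs))
  chunk <- 64L
  for (start in seq(1, length(xs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(xs))
    out[idx] <- counter_batch(object, xs[idx], want_grad = FALSE)$preds
  }
  out
}

#' @export
print.leaf_counter <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<leaf_counter (%s): input %dx%d, filters %s%s, %s>\n",
              cfg$architecture, cfg$input_size, cfg$input_size,
              paste(cfg$filters, collapse = "-"),
              if (cfg$architecture == "large")
                sprintf(", fc %d", cfg$fc_units) else "",
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.leaf_counter <- function(object, ...) {
  w <- object$weights
  n_par <- sum(vapply(w$conv_W, length, 1)) + sum(vapply(w$conv_b, length, 1)) +
    length(w$fc_W) + length(w$fc_b) + length(w$out_W) + 1
  cat(sprintf("Leaf-count CNN regressor (%s architecture)\n",
              object$config$architecture))
  cat(sprintf("  parameters: %d\n", n_par))
  cat(sprintf("  weight decay: %g, learning rate: %g (%s)\n",
              object$config$weight_decay, object$config$learning_rate,
              object$config$optimizer))
  if (!is.null(object$loss_history)) {
    lh <- object$loss_history
    cat(sprintf("  trained %d epochs; final train loss %.4f%s\n",
                nrow(lh), lh$train_loss[nrow(lh)],
                if (!is.na(lh$val_loss[nrow(lh)]))
                  sprintf(", held-out loss %.4f", lh$val_loss[nrow(lh)])
                else ""))
  }
  invisible(object)
}

#' @export
coef.leaf_counter <- function(object, ...) object$weights

#' @export
plot.leaf_counter <- function(x, ...) {
  lh <- x$loss_history
  if (is.null(lh)) stop("model has no loss history (untrained)", call. = FALSE)
  ylim <- range(c(lh$train_loss, lh$val_loss), na.rm = TRUE)
  plot(lh$epoch, lh$train_loss, type = "l", col = "steelblue", lwd = 2,
       xlab = "epoch", ylab = "mean squared count error", ylim = ylim, ...)
  if (any(!is.na(lh$val_loss)))
    graphics::lines(lh$epoch, lh$val_loss, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("train", "held-out"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Count-regression metrics
#'
#' The metric set reported for leaf-counting: predictions are integerized by
#' rounding half away from zero, then
#' \itemize{
#'   \item AbsCountDiff: mean (and sd) of |round(pred) - truth|,
#'   \item CountDiff: mean (and sd) of round(pred) - truth,
#'   \item MSE: mean squared integer difference,
#'   \item R^2: 1 - SS_res/SS_tot on the rounded predictions (can be
#'     negative when a predictor is worse than the truth mean),
#'   \item Agreement: percent of samples with round(pred) == truth.
#' }
#' Real-valued (unrounded) variants are kept alongside for transparency.
#'
#' @param preds Numeric predictions.
#' @param truths Numeric (integer) ground-truth counts.
#' @return An object of class `eval_metrics`.
#' @export
eval_metrics <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) > 0)
  r <- round_half_away(preds)
  d <- r - truths
  ss_tot <- sum((truths - mean(truths))^2)
  r2 <- if (ss_tot > 0) 1 - sum(d^2) / ss_tot else NA_real_
  structure(list(
    abs_count_diff_mean = mean(abs(d)),
    abs_count_diff_sd = stats::sd(abs(d)),
    count_diff_mean = mean(d),
    count_diff_sd = stats::sd(d),
    mse = mean(d^2),
    r_squared = r2,
    agreement_pct = 100 * mean(d == 0),
    mse_real = mean((preds - truths)^2),
    abs_count_diff_mean_real = mean(abs(preds - truths)),
    n = length(preds)), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "AbsCountDiff %.2f (%.2f)  CountDiff %.2f (%.2f)  MSE %.2f  R2 %s  Agreement %.0f%%\n",
    x$abs_count_diff_mean, x$abs_count_diff_sd, x$count_diff_mean,
    x$count_diff_sd, x$mse,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.2f", x$r_squared)),
    x$agreement_pct))
  invisible(x)
}

#' @export
as.data.frame.eval_metrics <- function(x, ...) {
  data.frame(abs_count_diff = x$abs_count_diff_mean,
             abs_count_diff_sd = x$abs_count_diff_sd,
             count_diff = x$count_diff_mean,
             count_diff_sd = x$count_diff_sd,
             mse = x$mse, r_squared = x$r_squared,
             agreement_pct = x$agreement_pct, n = x$n)
}

#' Evaluate a trained counter
#'
#' @param model A trained `leaf_counter`.
#' @param x List of image arrays.
#' @param y True counts.
#' @return An [eval_metrics()] object.
#' @export
evaluate_counter <- function(model, x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  eval_metrics(predict(model, x), y)
}

#' Load images for a manifest
#'
#' Reads every image referenced by a dataset manifest, optionally applies
#' the black-background masking convention (using each record's mask), and
#' resizes to the requested input size.
#'
#' @param manifest A `dataset_manifest`.
#' @param input_size Target side in pixels (images are bilinearly resized
#'   if needed).
#' @param mask_black Apply [apply_mask_black()] using the per-record masks.
#' @return A list with `x` (list of arrays) and `y` (integer counts).
#' @export
load_images <- function(manifest, input_size = NULL, mask_black = FALSE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  rec <- manifest$records
  xs <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    img <- read_image_png(file.path(manifest$dir, rec$filename[i]))
    if (mask_black) {
      if (is.na(rec$mask[i]))
        stop("mask_black requested but no mask for ", rec$filename[i],
             call. = FALSE)
      m <- read_mask_png(file.path(manifest$dir, rec$mask[i]))
      img <- apply_mask_black(img, m)
    }
    if (!is.null(input_size) && dim(img)[1] != input_size)
      img <- resize_bilinear_cpp(img, input_size, input_size)
    xs[[i]] <- img
  }
  list(x = xs, y = rec$leaf_count)
}
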