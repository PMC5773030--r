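#' Leaf-counting experiment drivers
#'
#' Runs one of the three experiment designs on top of the dataset builder
#' and the CNN counter:
#' \describe{
#'   \item{augmentation}{train on real data alone versus real data plus 1000
#'     synthetic rosettes (S2 preset), evaluate both on the real test split.
#'     Requires user-supplied real data; without it a synthetic stand-in
#'     plays the role of the real set and the report is flagged
#'     accordingly.}
#'   \item{generalization}{train purely on S12 (uniform 5--20 leaves, mixed
#'     backgrounds), evaluate on two sets with shifted count distributions
#'     (real sets if supplied, else S1/S2-style stand-ins), applying the
#'     black-background masking convention to the test images.}
#'   \item{interoperability}{train on S2 and evaluate on a count-range-
#'     matched set from the other domain (real if supplied, else an
#'     independently generated synthetic set), and vice versa with S1.}
#' }
#'
#' Each row of the report carries the full metric set plus the distribution
#' of signed count differences (the relative-count-difference histogram).
#'
#' @param name Experiment name.
#' @param real_dir Optional directory of real data in PRL-style layout
#'   (RGB PNG + count CSV + foreground masks); see [load_dataset()].
#' @param out_dir Optional directory for generated datasets and CSV reports
#'   (default: a temporary directory).
#' @param n_images Synthetic dataset size (default 1000, the preset size).
#' @param image_size Render / network input side, pixels. The presets use
#'   256; smaller sizes give fast desk-scale runs.
#' @param arch Architecture override (default: `"small"` for augmentation,
#'   `"large"` otherwise).
#' @param filters Filter-count override (useful for desk-scale runs).
#' @param epochs Training epochs.
#' @param seed Master seed; all dataset and training seeds derive from it.
#' @param blade_res Blade triangulation resolution.
#' @param verbose Print progress.
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(name = c("augmentation", "generalization",
                                    "interoperability"),
                           real_dir = NULL, out_dir = NULL,
                           n_images = 1000, image_size = 128,
                           arch = NULL, filters = NULL, epochs = 30,
                           seed = 1, blade_res = c(24, 8),
                           verbose = FALSE) {
  name <- match.arg(name)
  if (is.null(out_dir)) out_dir <- tempfile(paste0("rosettesim_", name, "_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arch <- arch %||% if (name == "augmentation") "small" else "large"
  standin <- is.null(real_dir)

  gen <- function(preset, tag, idx, ...) {
    d <- file.path(out_dir, tag)
    spec <- dataset_preset(preset, n_images = n_images,
                           image_size = image_size,
                           master_seed = derive_seed(seed, idx), ...)
    if (verbose) message("generating ", tag, " (", preset, ")")
    generate_dataset(spec, d, blade_res = blade_res)
  }
  new_model <- function(k) {
    cfg <- counter_config(architecture = arch, input_size = image_size,
                          filters = filters, epochs = epochs,
                          seed = derive_seed(seed, 1000 + k))
    build_counter(cfg)
  }
  fit <- function(model, data, k) {
    if (verbose) message("training model ", k)
    train_counter(model, data$x, data$y)
  }
  metric_row <- function(model, test, train_name, test_name) {
    preds <- predict(model, test$x)
    m <- eval_metrics(preds, test$y)
    row <- cbind(data.frame(training_data = train_name,
                            testing_data = test_name),
                 as.data.frame(m))
    hist <- as.data.frame(table(diff = round_half_away(preds) - test$y),
                          responseName = "count")
    list(row = row, hist = hist)
  }

  rows <- list(); hists <- list(); notes <- character(0)

  if (name == "augmentation") {
    if (standin) {
      notes <- c(notes, paste(
        "external data required for the real-data comparison;",
        "a synthetic stand-in (S2-style, independent seed) plays the",
        "role of the real dataset"))
      realm <- gen("S2", "standin_real", 11L)
      real_name <- "standin-real(S2-style)"
    } else {
      realm <- load_dataset(real_dir)
      real_name <- "real"
    }
    sp <- split_train_test(realm, 0.8, seed = derive_seed(seed, 21L))
    tr <- load_images(sp$train, image_size)
    te <- load_images(sp$test, image_size)
    s2 <- gen("S2", "S2", 12L)
    s2d <- load_images(s2, image_size)
    m0 <- fit(new_model(1L), tr, 1L)
    m1 <- fit(new_model(2L),
              list(x = c(tr$x, s2d$x), y = c(tr$y, s2d$y)), 2L)
    r0 <- metric_row(m0, te, real_name, paste0(real_name, "-test"))
    r1 <- metric_row(m1, te, paste0(real_name, " + S2"),
                     paste0(real_name, "-test"))
    rows <- list(r0$row, r1$row); hists <- list(r0$hist, r1$hist)
  } else if (name == "generalization") {
    s12 <- gen("S12", "S12", 13L)
    trd <- load_images(s12, image_size)
    model <- fit(new_model(1L), trd, 1L)
    if (standin) {
      notes <- c(notes, paste(
        "external data required for the real-data evaluation; synthetic",
        "S1/S2-style stand-ins with the two shifted count ranges are",
        "used instead"))
      t1 <- gen("S1", "standin_hi", 14L)
      t2 <- gen("S2", "standin_lo", 15L)
      n1 <- "standin-hi(S1-style,12-20)"; n2 <- "standin-lo(S2-style,5-13)"
    } else {
      stop_msg <- "real_dir must contain 'hi' and 'lo' subdirectories"
      if (!dir.exists(file.path(real_dir, "hi")) ||
          !dir.exists(file.path(real_dir, "lo")))
        stop(stop_msg, call. = FALSE)
      t1 <- load_dataset(file.path(real_dir, "hi"))
      t2 <- load_dataset(file.path(real_dir, "lo"))
      n1 <- "real-hi"; n2 <- "real-lo"
    }
    te1 <- load_images(t1, image_size, mask_black = TRUE)
    te2 <- load_images(t2, image_size, mask_black = TRUE)
    r1 <- metric_row(model, te1, "S12", n1)
    r2 <- metric_row(model, te2, "S12", n2)
    rows <- list(r1$row, r2$row); hists <- list(r1$hist, r2$hist)
  } else { # interoperability
    s2 <- gen("S2", "S2", 16L)
    s1 <- gen("S1", "S1", 17L)
    if (standin) {
      notes <- c(notes, paste(
        "external data required for the cross-domain runs; independently",
        "generated synthetic sets with matched count ranges stand in for",
        "the real data"))
      o2 <- gen("S2", "other_lo", 18L)
      o1 <- gen("S1", "other_hi", 19L)
      n2 <- "range-matched(5-13)"; n1 <- "range-matched(12-20)"
    } else {
      o2 <- load_dataset(real_dir); o1 <- o2
      n2 <- n1 <- "real"
    }
    m2 <- fit(new_model(1L), load_images(s2, image_size), 1L)
    m1 <- fit(new_model(2L), load_images(s1, image_size), 2L)
    r2 <- metric_row(m2, load_images(o2, image_size), "S2", n2)
    r1 <- metric_row(m1, load_images(o1, image_size), "S1", n1)
    rows <- list(r2$row, r1$row); hists <- list(r2$hist, r1$hist)
  }

  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  for (i in seq_along(hists))
    utils::write.csv(hists[[i]],
                     file.path(out_dir, sprintf("hist_row%d.csv", i)),
                     row.names = FALSE)
  structure(list(name = name, standin = standin, notes = notes,
                 metrics = metrics, histograms = hists, out_dir = out_dir),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("== %s experiment%s ==\n", x$name,
              if (x$standin) " (synthetic stand-in)" else ""))
  for (nt in x$notes) cat("note:", nt, "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Training-set-size sweep
#'
#' Trains the counter on nested subsets of a synthetic training pool and
#' evaluates each on a common held-out set, repeating over several seeds.
#' Generalization performance is expected to improve (median absolute count
#' difference not to increase) with larger training sets.
#'
#' @param sizes Training-set sizes (default `c(100, 250, 500, 1000)`).
#' @param seeds Seeds to repeat over (default `1:3`).
#' @param n_test Held-out set size per seed.
#' @param image_size Render / input side, pixels.
#' @param filters Filter counts (desk-scale default `c(8, 16, 16)`).
#' @param epochs Epochs per fit.
#' @param out_dir Scratch directory for the generated datasets.
#' @param blade_res Blade triangulation resolution.
#' @param verbose Print progress.
#' @return Data frame with one row per (size, seed):
#'   `size`, `seed`, `abs_count_diff`, `agreement_pct`.
#' @export
training_size_sweep <- function(sizes = c(100, 250, 500, 1000), seeds = 1:3,
                                n_test = 200, image_size = 48,
                                filters = c(8, 16, 16), epochs = 12,
                                out_dir = NULL, blade_res = c(12, 4),
                                verbose = FALSE) {
  if (is.null(out_dir)) out_dir <- tempfile("rosettesim_sweep_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sd in seeds) {
    pool_spec <- dataset_preset("S12", n_images = max(sizes) + n_test,
                                image_size = image_size,
                                master_seed = derive_seed(sd, 7L))
    pool <- generate_dataset(pool_spec, file.path(out_dir, paste0("pool", sd)),
                             blade_res = blade_res)
    dat <- load_images(pool, image_size)
    test_idx <- seq_len(n_test)
    te <- list(x = dat$x[test_idx], y = dat$y[test_idx])
    for (sz in sizes) {
      tr_idx <- n_test + seq_len(sz)
      cfg <- counter_config("small", input_size = image_size,
                            filters = filters, epochs = epochs,
                            seed = derive_seed(sd, 100L + sz))
      model <- train_counter(build_counter(cfg),
                             dat$x[tr_idx], dat$y[tr_idx])
      m <- evaluate_counter(model, te$x, te$y)
      if (verbose)
        message(sprintf("seed %d size %4d: AbsCountDiff %.3f", sd, sz,
                        m$abs_count_diff_mean))
      rows[[length(rows) + 1L]] <-
        data.frame(size = sz, seed = sd,
                   abs_count_diff = m$abs_count_diff_mean,
                   agreement_pct = m$agreement_pct)
    }
  }
  do.call(rbind, rows)
}
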