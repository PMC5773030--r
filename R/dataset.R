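#' Dataset specification
#'
#' Describes one synthetic dataset: how many plants, the leaf-count range,
#' the background policy and the render geometry. Three presets are pinned:
#' \describe{
#'   \item{S1}{1000 images, 12--20 leaves, soil background.}
#'   \item{S2}{1000 images, 5--13 leaves, soil background.}
#'   \item{S12}{1000 images, 5--20 leaves, mixed background (random RGB with
#'     probability 0.5, else soil).}
#' }
#' All presets render 256 x 256 images with the plant diameter between half
#' and the full image side (1:2 to 1:1).
#'
#' @param name Dataset name.
#' @param n_images Number of samples (>= 1).
#' @param leaf_count_range Inclusive integer range of leaf counts.
#' @param background_mode See [render_config()].
#' @param image_size Image side in pixels.
#' @param scale_ratio_range Plant-diameter / image-side interval.
#' @param master_seed Integer seed from which all per-sample seeds derive.
#' @param mixed_p Random-background probability for `"mixed"` mode.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(name, n_images, leaf_count_range,
                         background_mode = "soil", image_size = 256,
                         scale_ratio_range = c(0.5, 1), master_seed = 1,
                         mixed_p = 0.5) {
  stopifnot(n_images >= 1)
  structure(list(name = name, n_images = as.integer(n_images),
                 leaf_count_range = as.integer(leaf_count_range),
                 background_mode = background_mode,
                 image_size = as.integer(image_size),
                 scale_ratio_range = scale_ratio_range,
                 master_seed = as.integer(master_seed),
                 mixed_p = mixed_p),
            class = "dataset_spec")
}

#' @rdname dataset_spec
#' @param preset `"S1"`, `"S2"` or `"S12"`.
#' @param ... Overrides passed on to [dataset_spec()] (e.g. `n_images`,
#'   `master_seed`, `image_size`).
#' @export
dataset_preset <- function(preset = c("S1", "S2", "S12"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    S1  = list(name = "S1", n_images = 1000L,
               leaf_count_range = c(12L, 20L), background_mode = "soil"),
    S2  = list(name = "S2", n_images = 1000L,
               leaf_count_range = c(5L, 13L), background_mode = "soil"),
    S12 = list(name = "S12", n_images = 1000L,
               leaf_count_range = c(5L, 20L), background_mode = "mixed"))
  do.call(dataset_spec, utils::modifyList(base, list(...)))
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf(
    "<dataset_spec %s: %d images, %d-%d leaves, %s background, %dpx>\n",
    x$name, x$n_images, x$leaf_count_range[1], x$leaf_count_range[2],
    x$background_mode, x$image_size))
  invisible(x)
}

save_dataset_spec <- function(spec, path) {
  txt <- c(sprintf("name: %s", spec$name),
           sprintf("n_images: %d", spec$n_images),
           sprintf("leaf_count_range: [%d, %d]", spec$leaf_count_range[1],
                   spec$leaf_count_range[2]),
           sprintf("background_mode: %s", spec$background_mode),
           sprintf("image_size: %d", spec$image_size),
           sprintf("scale_ratio_range: [%.17g, %.17g]",
                   spec$scale_ratio_range[1], spec$scale_ratio_range[2]),
           sprintf("master_seed: %d", spec$master_seed),
           sprintf("mixed_p: %.17g", spec$mixed_p))
  writeLines(txt, path)
}

#' Generate a synthetic dataset
#'
#' Draws `n_images` plants from the stochastic rosette model, renders each
#' to a PNG image plus a foreground-mask PNG, and writes a labels CSV
#' (`filename,leaf_count`), a provenance manifest CSV and the spec. Every
#' per-sample seed derives deterministically from the spec's master seed, so
#' regeneration from the same spec is bit-identical. A sample whose render
#' leaves any blade without a foreground pixel is rejected and regenerated
#' from the next derived seed.
#'
#' @param spec A [dataset_spec()].
#' @param dir Output directory (created if needed).
#' @param fs A [growth_function_set()].
#' @param render Logical; `FALSE` skips rasterization and writes labels and
#'   manifest only (fast label-distribution studies).
#' @param blade_res Blade triangulation resolution (see [render_config()]).
#' @param progress Print progress every 100 samples.
#' @return A `dataset_manifest`: the spec plus a data frame with one row per
#'   sample (`filename`, `mask`, `leaf_count`, `seed`, `background_kind`,
#'   `scale_ratio`).
#' @export
generate_dataset <- function(spec, dir, fs = default_function_set(),
                             render = TRUE, blade_res = c(24, 8),
                             progress = FALSE) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  cfg <- render_config(image_size = spec$image_size,
                       scale_ratio_range = spec$scale_ratio_range,
                       background_mode = spec$background_mode,
                       mixed_p = spec$mixed_p,
                       blade_res = blade_res)
  scfg <- stochastic_config(leaf_count_range = spec$leaf_count_range)
  n <- spec$n_images
  rows <- vector("list", n)
  width <- max(4L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    sample_seed <- derive_seed(spec$master_seed, i)
    stem <- sprintf(paste0("%s_%0", width, "d"), tolower(spec$name), i)
    fn <- paste0(stem, ".png"); mfn <- paste0(stem, "_mask.png")
    if (render) {
      smp <- NULL
      for (attempt in 1:25) {
        pseed <- derive_seed(sample_seed, attempt)
        params <- sample_rosette_params(scfg, seed = pseed)
        plant <- build_rosette(params, fs)
        smp <- render(plant$scene, cfg, fs, seed = derive_seed(pseed, 1L))
        if (smp$all_blades_visible) break
      }
      if (!smp$all_blades_visible)
        stop("failed to render a sample with all blades visible", call. = FALSE)
      write_sample_png(smp, file.path(dir, fn), file.path(dir, mfn))
      rows[[i]] <- data.frame(filename = fn, mask = mfn,
                              leaf_count = smp$leaf_count,
                              seed = sample_seed,
                              background_kind = smp$background_kind,
                              scale_ratio = smp$scale_ratio)
    } else {
      pseed <- derive_seed(sample_seed, 1L)
      params <- sample_rosette_params(scfg, seed = pseed)
      rows[[i]] <- data.frame(filename = fn, mask = mfn,
                              leaf_count = params$target_leaf_count,
                              seed = sample_seed,
                              background_kind = NA_character_,
                              scale_ratio = NA_real_)
    }
    if (progress && i %% 100 == 0) message(sprintf("  %d / %d", i, n))
  }
  records <- do.call(rbind, rows)
  utils::write.csv(records[, c("filename", "leaf_count")],
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(records, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  save_dataset_spec(spec, file.path(dir, "spec.yaml"))
  structure(list(spec = spec, dir = dir, records = records),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest: %d samples in %s>\n", nrow(x$records),
              x$dir %||% "<memory>"))
  tab <- table(x$records$leaf_count)
  cat("leaf-count histogram:\n")
  print(tab)
  invisible(x)
}

#' Load a dataset directory
#'
#' Accepts both the layout written by [generate_dataset()] (a `labels.csv`
#' with header `filename,leaf_count`, plus `<stem>_mask.png` masks) and a
#' PRL-style layout: RGB PNGs, a leaf-count CSV (with or without header) and
#' per-image foreground masks named `<stem>_label.png`, `<stem>_fg.png` or
#' `<stem>_mask.png`. Unknown extra files are ignored.
#'
#' @param dir Directory path.
#' @param labels_csv Optional explicit CSV path (default: `labels.csv` in
#'   `dir`, else the single `*.csv` file found there).
#' @return A `dataset_manifest`.
#' @export
load_dataset <- function(dir, labels_csv = NULL) {
  if (is.null(labels_csv)) {
    cand <- file.path(dir, "labels.csv")
    if (!file.exists(cand)) {
      csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
      csvs <- csvs[basename(csvs) != "manifest.csv"]
      if (length(csvs) != 1)
        stop("no labels CSV found in ", dir, call. = FALSE)
      cand <- csvs
    }
    labels_csv <- cand
  }
  if (!file.exists(labels_csv))
    stop("labels CSV not found: ", labels_csv, call. = FALSE)
  first <- readLines(labels_csv, n = 1)
  has_header <- grepl("filename", first, ignore.case = TRUE)
  df <- utils::read.csv(labels_csv, header = has_header,
                        stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) < 2)
      stop("labels CSV must have two columns (filename, count)",
           call. = FALSE)
    names(df)[1:2] <- c("filename", "leaf_count")
  }
  if (!all(c("filename", "leaf_count") %in% names(df)))
    stop("labels CSV must contain 'filename' and 'leaf_count' columns",
         call. = FALSE)
  counts <- suppressWarnings(as.numeric(df$leaf_count))
  bad <- which(is.na(counts) | counts != floor(counts))
  if (length(bad))
    stop(sprintf("non-integer leaf count at line %d of %s",
                 bad[1] + as.integer(has_header), labels_csv), call. = FALSE)
  df$leaf_count <- as.integer(counts)
  missing <- !file.exists(file.path(dir, df$filename))
  if (any(missing))
    stop("label references missing image: ", df$filename[which(missing)[1]],
         call. = FALSE)
  stem <- sub("\\.png$", "", df$filename)
  mask <- rep(NA_character_, nrow(df))
  for (suf in c("_mask.png", "_label.png", "_fg.png")) {
    cand <- paste0(stem, suf)
    hit <- is.na(mask) & file.exists(file.path(dir, cand))
    mask[hit] <- cand[hit]
  }
  df$mask <- mask
  spec <- if (file.exists(file.path(dir, "spec.yaml"))) {
    y <- yaml::read_yaml(file.path(dir, "spec.yaml"))
    dataset_spec(y$name, y$n_images, y$leaf_count_range, y$background_mode,
                 y$image_size, as.numeric(y$scale_ratio_range),
                 y$master_seed, y$mixed_p)
  } else NULL
  structure(list(spec = spec, dir = dir, records = df),
            class = "dataset_manifest")
}

#' Split a dataset into train and test sets
#'
#' Random, disjoint, exhaustive split. The training set receives
#' `floor(fraction * n)` records (ties toward test); the split is
#' deterministic given the seed.
#'
#' @param manifest A `dataset_manifest`.
#' @param fraction Training fraction in (0, 1); default 0.8 (the 80/20
#'   protocol).
#' @param seed Integer seed.
#' @return A list with `train` and `test` manifests.
#' @export
split_train_test <- function(manifest, fraction = 0.8, seed = 1) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            fraction > 0, fraction < 1)
  n <- nrow(manifest$records)
  n_train <- floor(fraction * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  mk <- function(rows) {
    out <- manifest
    out$records <- manifest$records[rows, , drop = FALSE]
    rownames(out$records) <- NULL
    out
  }
  list(train = mk(sort(idx)), test = mk(setdiff(seq_len(n), idx)))
}

#' Label histogram of a dataset
#'
#' @param manifest A `dataset_manifest`.
#' @return A table of leaf-count frequencies.
#' @export
label_histogram <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  table(manifest$records$leaf_count)
}
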