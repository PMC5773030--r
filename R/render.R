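#' Render configuration
#'
#' Policies used to rasterize a scene into a labeled training image:
#' top-down (nadir) orthographic camera, random plant-diameter/image-side
#' scale ratio, and a configurable flat background.
#'
#' Background modes: `"soil"` (flat brown approximating soil), `"random_rgb"`
#' (a color drawn uniformly from the 8-bit RGB cube per image), `"mixed"`
#' (random with probability `mixed_p`, else soil) and `"black"` (the masking
#' convention used when testing across domains).
#'
#' @param image_size Output image side, pixels (square; default 256).
#' @param scale_ratio_range Interval of plant-diameter / image-side ratios
#'   drawn uniformly per image; default `c(0.5, 1)` (1:2 to 1:1).
#' @param background_mode One of `"soil"`, `"random_rgb"`, `"mixed"`,
#'   `"black"`.
#' @param mixed_p Probability of a random background in `"mixed"` mode.
#' @param soil_color,leaf_color_base RGB triples in \[0, 1\].
#' @param color_jitter Per-leaf relative brightness jitter amplitude
#'   (default 0.10, i.e. a uniform factor in \[0.9, 1.1\]).
#' @param supersample Supersampling factor for anti-aliasing (default 2;
#'   the mask is computed at final resolution by majority rule).
#' @param blade_res Integer pair: triangulation segments along and across
#'   the blade midrib (default `c(24, 8)`).
#' @return An object of class `render_config`.
#' @export
render_config <- function(image_size = 256,
                          scale_ratio_range = c(0.5, 1),
                          background_mode = c("soil", "random_rgb", "mixed",
                                              "black"),
                          mixed_p = 0.5,
                          soil_color = c(110, 80, 55) / 255,
                          leaf_color_base = c(70, 130, 60) / 255,
                          color_jitter = 0.10,
                          supersample = 2,
                          blade_res = c(24, 8)) {
  background_mode <- match.arg(background_mode)
  stopifnot(length(scale_ratio_range) == 2,
            scale_ratio_range[1] > 0, scale_ratio_range[2] <= 1,
            scale_ratio_range[1] <= scale_ratio_range[2],
            mixed_p >= 0, mixed_p <= 1, image_size >= 8, supersample >= 1)
  structure(list(image_size = as.integer(image_size),
                 scale_ratio_range = scale_ratio_range,
                 background_mode = background_mode, mixed_p = mixed_p,
                 soil_color = soil_color, leaf_color_base = leaf_color_base,
                 color_jitter = color_jitter,
                 supersample = as.integer(supersample),
                 blade_res = as.integer(blade_res)),
            class = "render_config")
}

# triangulate a scene into (verts, z, tris, tri_prim) in model units;
# blades become a grid of quads over the midrib x contour, cylinders become
# flat ribbons (their exact silhouette under the nadir camera)
triangulate_scene <- function(scene, fs, blade_res = c(24, 8)) {
  stopifnot(inherits(scene, "scene"))
  vs <- list(); ts <- list(); tp <- list()
  nv <- 0L
  for (pi in seq_along(scene$primitives)) {
    pr <- scene$primitives[[pi]]
    if (pr$type == "cylinder") {
      d <- pr$tip - pr$base
      horiz <- c(d[1], d[2], 0)
      hn <- sqrt(sum(horiz^2))
      perp <- if (hn < 1e-12) c(1, 0, 0) else
        c(-horiz[2], horiz[1], 0) / hn
      v <- rbind(pr$base + perp * pr$r_base, pr$base - perp * pr$r_base,
                 pr$tip + perp * pr$r_tip, pr$tip - perp * pr$r_tip)
      tri <- rbind(c(1, 2, 3), c(2, 4, 3)) + nv
    } else { # blade
      nm <- blade_res[1]; na <- blade_res[2]
      ss <- seq(0, 1, length.out = nm + 1)
      ww <- seq(-1, 1, length.out = na + 1)
      half <- pr$length * eval_curve(fs$f_lw, ss)
      H <- pr$frame[, "H"]; L <- pr$frame[, "L"]
      # grid rows: along midrib; columns: across
      v <- matrix(0, (nm + 1) * (na + 1), 3)
      k <- 0L
      for (i in seq_len(nm + 1)) {
        along <- pr$origin + H * (ss[i] * pr$length)
        for (j in seq_len(na + 1)) {
          k <- k + 1L
          v[k, ] <- along + L * (ww[j] * half[i])
        }
      }
      idx <- function(i, j) (i - 1L) * (na + 1L) + j
      tri <- matrix(0L, 2L * nm * na, 3)
      r <- 0L
      for (i in seq_len(nm)) for (j in seq_len(na)) {
        r <- r + 1L
        tri[r, ] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
        r <- r + 1L
        tri[r, ] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      }
      tri <- tri + nv
    }
    vs[[length(vs) + 1L]] <- v
    ts[[length(ts) + 1L]] <- tri
    tp[[length(tp) + 1L]] <- rep(pi, nrow(tri))
    nv <- nv + nrow(v)
  }
  list(verts = do.call(rbind, vs),
       tris = do.call(rbind, ts),
       tri_prim = unlist(tp))
}

#' Projected plant diameter
#'
#' The diameter of a scene's vertical (top-down) projection: the maximum
#' pairwise distance between projected surface points, computed on the
#' convex hull of the triangulated geometry. This is the quantity the scale
#' policy controls (plant diameter relative to image side), and it is
#' invariant under rotation of the scene about the vertical axis.
#'
#' @param scene A `scene`.
#' @param fs A [growth_function_set()] (blade contours are needed to
#'   triangulate).
#' @param blade_res Blade triangulation resolution.
#' @return Diameter in model units.
#' @export
compute_diameter <- function(scene, fs = default_function_set(),
                             blade_res = c(24, 8)) {
  stopifnot(inherits(scene, "scene"))
  if (length(scene$primitives) == 0)
    stop("cannot compute the diameter of an empty scene", call. = FALSE)
  g <- triangulate_scene(scene, fs, blade_res)
  xy <- g$verts[, 1:2, drop = FALSE]
  if (nrow(xy) < 3) return(max(stats::dist(xy)))
  h <- grDevices::chull(xy)
  max(stats::dist(xy[h, , drop = FALSE]))
}

#' Render a scene to a labeled sample
#'
#' Orthographic nadir projection with z-buffered, supersampled triangle
#' rasterization. The plant is centered, scaled so that its projected
#' diameter is a uniformly drawn fraction of the image side
#' (`scale_ratio_range`), composited over the configured flat background,
#' and anti-aliased at mask (foreground) pixels; non-mask pixels equal the
#' background color exactly. Each leaf receives a brightness jitter around
#' the base leaf color. Deterministic given `(scene, cfg, seed)`.
#'
#' @param scene A `scene`.
#' @param cfg A [render_config()].
#' @param fs The [growth_function_set()] used to build the scene.
#' @param seed Optional integer seed for the render draws (scale ratio,
#'   background, color jitter).
#' @return An object of class `labeled_sample`: list with `image`
#'   (image_size x image_size x 3 array in \[0,1\]), `mask` (logical
#'   matrix), `leaf_count`, `background_kind` (`"soil"`, `"random_rgb"` or
#'   `"black"`), `background_color`, `scale_ratio`, `all_blades_visible`
#'   (every blade owns at least one foreground pixel), `render_seed`.
#' @export
render <- function(scene, cfg = render_config(), fs = default_function_set(),
                   seed = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(cfg, "render_config"))
  if (!is.null(seed)) set.seed(seed)
  S <- cfg$image_size

  ratio <- stats::runif(1, cfg$scale_ratio_range[1], cfg$scale_ratio_range[2])
  bg_kind <- switch(cfg$background_mode,
    soil = "soil",
    black = "black",
    random_rgb = "random_rgb",
    mixed = if (stats::runif(1) < cfg$mixed_p) "random_rgb" else "soil")
  bg <- switch(bg_kind,
    soil = cfg$soil_color,
    black = c(0, 0, 0),
    random_rgb = stats::runif(3))

  g <- triangulate_scene(scene, fs, cfg$blade_res)
  xy <- g$verts[, 1:2, drop = FALSE]
  h <- if (nrow(xy) >= 3) grDevices::chull(xy) else seq_len(nrow(xy))
  D <- max(stats::dist(xy[h, , drop = FALSE]))
  if (!is.finite(D) || D <= 0) D <- 1e-6
  ctr <- c((min(xy[, 1]) + max(xy[, 1])) / 2, (min(xy[, 2]) + max(xy[, 2])) / 2)
  rmax <- sqrt(max((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
  ppu <- ratio * S / D
  ppu <- min(ppu, (S / 2 - 1.5) / max(rmax, 1e-9)) # guarantee in-frame
  px <- (xy[, 1] - ctr[1]) * ppu + S / 2
  py <- (xy[, 2] - ctr[2]) * ppu + S / 2

  # per-primitive flat colors: leaves jittered per node, stem organs greenish
  prims <- scene$primitives
  organs <- vapply(prims, `[[`, "", "organ")
  nodes <- vapply(prims, function(p) as.numeric(p$node %||% NA_real_),
                  numeric(1))
  leaf_nodes <- sort(unique(nodes[organs %in% c("blade", "petiole")]))
  jit <- stats::runif(max(1, length(leaf_nodes)),
                      1 - cfg$color_jitter, 1 + cfg$color_jitter)
  col <- matrix(0, length(prims), 3)
  for (i in seq_along(prims)) {
    base_col <- cfg$leaf_color_base
    f <- 1
    if (organs[i] %in% c("blade", "petiole") && !is.na(nodes[i]))
      f <- jit[match(nodes[i], leaf_nodes)]
    if (organs[i] == "petiole") base_col <- base_col * 0.85
    if (organs[i] %in% c("internode", "segment")) base_col <- base_col * 0.7
    col[i, ] <- pmin(pmax(base_col * f, 0), 1)
  }

  ras <- rasterize_cpp(cbind(px, py), g$verts[, 3], g$tris - 1L,
                       as.integer(g$tri_prim - 1L), col,
                       S, cfg$supersample, bg)
  blade_idx <- which(organs == "blade")
  visible <- ras$prim_mask_pixels[blade_idx] >= 1L
  structure(list(image = ras$image,
                 mask = ras$mask,
                 leaf_count = length(blade_idx),
                 background_kind = bg_kind,
                 background_color = bg,
                 scale_ratio = ratio,
                 all_blades_visible = all(visible),
                 render_seed = if (is.null(seed)) NA_integer_
                               else as.integer(seed)),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf(
    "<labeled_sample: %dx%d, %d leaves, %s background, scale %.2f>\n",
    nrow(x$mask), ncol(x$mask), x$leaf_count, x$background_kind,
    x$scale_ratio))
  invisible(x)
}

#' Set background pixels to black
#'
#' The masking convention used when a network trained on synthetic images is
#' evaluated on real photographs (or vice versa): foreground pixels are kept,
#' background pixels are zeroed using the segmentation mask.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param mask H x W logical (or 0/1) matrix; `TRUE` = plant.
#' @return The masked image array.
#' @export
apply_mask_black <- function(image, mask) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (!all(dim(mask) == d[1:2]))
    stop("mask dimensions do not match the image", call. = FALSE)
  m <- array(rep(as.logical(mask), 3), dim = d)
  image[!m] <- 0
  image
}

#' Write / read labeled sample files
#'
#' PNG serialization: 8-bit RGB for images, 8-bit single-channel 0/255 for
#' masks.
#'
#' @param sample A `labeled_sample`.
#' @param image_path,mask_path Output paths.
#' @export
write_sample_png <- function(sample, image_path, mask_path = NULL) {
  png::writePNG(sample$image, image_path)
  if (!is.null(mask_path))
    png::writePNG(matrix(as.numeric(sample$mask), nrow(sample$mask)),
                  mask_path)
  invisible(image_path)
}

#' @rdname write_sample_png
#' @param path PNG path to read.
#' @return `read_image_png` returns an H x W x 3 array in \[0,1\];
#'   `read_mask_png` a logical matrix.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname write_sample_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
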