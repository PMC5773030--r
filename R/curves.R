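#' Control-point function curve
#'
#' A deterministic scalar function on \[0, 1\] defined by ordered control
#' points and monotone piecewise-cubic (Fritsch-Carlson) interpolation.
#' These curves stand in for the hand-drawn empirical functions of the
#' rosette model: final blade length, blade elongation over time, the blade
#' contour, and the leaf inclination angle.
#'
#' Monotone interpolation guarantees no overshoot between control points, so
#' a curve whose ordinates are non-negative stays non-negative everywhere --
#' a requirement for quantities such as lengths and widths.
#'
#' @param u Numeric vector of control abscissae. Must be strictly increasing,
#'   starting at 0 and ending at 1.
#' @param v Numeric vector of control ordinates, same length as `u`.
#' @return An object of class `function_curve`.
#' @examples
#' fc <- function_curve(c(0, 0.5, 1), c(0, 0.2, 1))
#' eval_curve(fc, 0.5)  # exactly 0.2
#' @export
function_curve <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) < 2L)
    stop("a function_curve needs at least 2 control points", call. = FALSE)
  if (length(u) != length(v))
    stop("control abscissae and ordinates differ in length", call. = FALSE)
  if (any(diff(u) <= 0))
    stop("control abscissae must be strictly increasing", call. = FALSE)
  if (abs(u[1]) > 1e-12 || abs(u[length(u)] - 1) > 1e-12)
    stop("control abscissae must start at 0 and end at 1", call. = FALSE)
  u[1] <- 0; u[length(u)] <- 1
  structure(list(u = u, v = v), class = "function_curve")
}

#' Evaluate a function curve
#'
#' Evaluates the monotone piecewise-cubic interpolant through the curve's
#' control points. The abscissa is clamped into \[0, 1\] first. Evaluation at
#' a control abscissa returns its ordinate exactly; evaluation is
#' deterministic (bit-identical for identical inputs).
#'
#' @param curve A [function_curve()].
#' @param u Numeric vector of evaluation abscissae (clamped to \[0, 1\]).
#' @return Numeric vector of curve values.
#' @export
eval_curve <- function(curve, u) {
  stopifnot(inherits(curve, "function_curve"))
  u <- pmin(pmax(as.numeric(u), 0), 1)
  f <- stats::splinefun(curve$u, curve$v, method = "monoH.FC")
  f(u)
}

#' @export
print.function_curve <- function(x, ...) {
  cat(sprintf("<function_curve: %d control points on [0,1]>\n", length(x$u)))
  invisible(x)
}

#' Growth function set
#'
#' Bundles the four empirical functions of the rosette model plus the two
#' petiole constants. All lengths are in arbitrary model units; the render
#' scale policy resolves them to pixels.
#'
#' \describe{
#'   \item{f_lmax}{final blade length as a function of normalized node
#'     position (node number / maximum leaf count), model units.}
#'   \item{f_l}{relative blade length as a function of normalized leaf age;
#'     must be non-decreasing with f_l(0) = 0 and f_l(1) = 1.}
#'   \item{f_lw}{blade half-width / length ratio as a function of relative
#'     position x along the midrib; f_lw(0) = f_lw(1) = 0 so the blade
#'     tapers at base and tip.}
#'   \item{f_ang}{leaf inclination angle (degrees pitched down from the
#'     vertical stem axis) as a function of normalized node position;
#'     values in \[0, 90\].}
#' }
#'
#' @param f_lmax,f_l,f_lw,f_ang [function_curve()] objects.
#' @param petiole_length_fraction Petiole length as a fraction of blade
#'   length (default 0.5).
#' @param petiole_width Constant petiole width, model units (default 0.02).
#' @param max_node Leaf count used to normalize node numbers (default 20,
#'   the model's maximum).
#' @param maturation_plastochrons Leaf age, in plastochrons, at which a
#'   blade reaches full size; older ages clamp to 1 (default 8).
#' @return An object of class `growth_function_set`.
#' @export
growth_function_set <- function(f_lmax, f_l, f_lw, f_ang,
                                petiole_length_fraction = 0.5,
                                petiole_width = 0.02,
                                max_node = 20,
                                maturation_plastochrons = 8) {
  for (nm in c("f_lmax", "f_l", "f_lw", "f_ang")) {
    cv <- get(nm)
    if (!inherits(cv, "function_curve"))
      stop(sprintf("%s must be a function_curve", nm), call. = FALSE)
  }
  grid <- seq(0, 1, length.out = 201)
  fl <- eval_curve(f_l, grid)
  if (any(diff(fl) < -1e-9))
    stop("f_l must be non-decreasing on [0,1]", call. = FALSE)
  if (abs(eval_curve(f_l, 0)) > 1e-9 || abs(eval_curve(f_l, 1) - 1) > 1e-9)
    stop("f_l must satisfy f_l(0)=0 and f_l(1)=1", call. = FALSE)
  if (abs(eval_curve(f_lw, 0)) > 1e-9 || abs(eval_curve(f_lw, 1)) > 1e-9)
    stop("f_lw must vanish at both ends (blade tapers)", call. = FALSE)
  ang <- eval_curve(f_ang, grid)
  if (any(ang < -1e-9) || any(ang > 90 + 1e-9))
    stop("f_ang must stay within [0, 90] degrees", call. = FALSE)
  structure(list(f_lmax = f_lmax, f_l = f_l, f_lw = f_lw, f_ang = f_ang,
                 petiole_length_fraction = petiole_length_fraction,
                 petiole_width = petiole_width,
                 max_node = max_node,
                 maturation_plastochrons = maturation_plastochrons),
            class = "growth_function_set")
}

#' Default growth functions
#'
#' Curves drawn to match the qualitative shapes reported for young
#' Arabidopsis rosettes: a sigmoidal elongation curve, a final-length
#' profile rising from the first nodes to a mid-rosette maximum and then
#' declining, an ovate blade contour with its widest point just past the
#' middle of the midrib, and an inclination angle decreasing with node
#' number (older leaves lie flatter). Control points are also shipped as a
#' plain-text config (`inst/extdata/default_curves.yaml`); users may
#' substitute their own measured curves.
#'
#' @return A [growth_function_set()].
#' @export
default_function_set <- function() {
  path <- system.file("extdata", "default_curves.yaml", package = "rosettesim",
                      mustWork = TRUE)
  load_function_set(path)
}

#' Blade length of leaf n at age t
#'
#' The blade length of the leaf at node `n` and normalized age `t` is the
#' product of the final length for that node position, the relative
#' elongation at that age, and the per-leaf stochastic size multiplier:
#' `x_mult * f_lmax(n / max_node) * f_l(t)`.
#'
#' @param fs A [growth_function_set()].
#' @param n Node index (1-based leaf number along the stem).
#' @param t Normalized leaf age in \[0, 1\] (1 = fully grown).
#' @param x_mult Per-leaf size multiplier (> 0), default 1.
#' @return Blade length, model units.
#' @export
leaf_length <- function(fs, n, t, x_mult = 1) {
  stopifnot(inherits(fs, "growth_function_set"), all(x_mult > 0))
  n_norm <- pmin(pmax(n / fs$max_node, 0), 1)
  x_mult * eval_curve(fs$f_lmax, n_norm) * eval_curve(fs$f_l, t)
}

#' Blade width at relative midrib position x
#'
#' The blade outline is shape-invariant under growth: the full width at
#' relative position `x` from the blade base is the current blade length
#' times twice the half-width contour `f_lw(x)`, so
#' `width = 2 * leaf_length(fs, n, t, x_mult) * f_lw(x)`.
#'
#' @inheritParams leaf_length
#' @param x Relative distance from the blade base along the midrib, \[0, 1\].
#' @return Full blade width at `x`, model units.
#' @export
leaf_width <- function(fs, n, t, x, x_mult = 1) {
  2 * leaf_length(fs, n, t, x_mult) * eval_curve(fs$f_lw, x)
}

#' Save / load growth function sets
#'
#' Plain-text (YAML) serialization of a [growth_function_set()]: each curve
#' is a list of `[u, v]` control points written at full double precision, so
#' a set round-trips losslessly.
#'
#' @param fs A [growth_function_set()].
#' @param path File path.
#' @return `save_function_set` returns `path` invisibly;
#'   `load_function_set` returns a [growth_function_set()].
#' @export
save_function_set <- function(fs, path) {
  stopifnot(inherits(fs, "growth_function_set"))
  fmt_curve <- function(cv) {
    paste0(vapply(seq_along(cv$u), function(i)
      sprintf("  - [%.17g, %.17g]", cv$u[i], cv$v[i]), character(1)),
      collapse = "\n")
  }
  txt <- paste0(
    "f_lmax:\n", fmt_curve(fs$f_lmax), "\n",
    "f_l:\n", fmt_curve(fs$f_l), "\n",
    "f_lw:\n", fmt_curve(fs$f_lw), "\n",
    "f_ang:\n", fmt_curve(fs$f_ang), "\n",
    sprintf("petiole_length_fraction: %.17g\n", fs$petiole_length_fraction),
    sprintf("petiole_width: %.17g\n", fs$petiole_width),
    sprintf("max_node: %.17g\n", fs$max_node),
    sprintf("maturation_plastochrons: %.17g\n", fs$maturation_plastochrons))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname save_function_set
#' @export
load_function_set <- function(path) {
  y <- yaml::read_yaml(path)
  curve_from <- function(pts) {
    m <- do.call(rbind, lapply(pts, as.numeric))
    function_curve(m[, 1], m[, 2])
  }
  growth_function_set(
    f_lmax = curve_from(y$f_lmax),
    f_l    = curve_from(y$f_l),
    f_lw   = curve_from(y$f_lw),
    f_ang  = curve_from(y$f_ang),
    petiole_length_fraction = y$petiole_length_fraction,
    petiole_width = y$petiole_width,
    max_node = y$max_node,
    maturation_plastochrons = y$maturation_plastochrons)
}
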