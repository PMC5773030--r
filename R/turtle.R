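#' @useDynLib rosettesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Rodrigues rotation of vector v about unit axis k by ang degrees
rotate_about <- function(v, k, ang) {
  th <- ang * pi / 180
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_turtle <- function() {
  list(pos = c(0, 0, 0),
       H = c(0, 0, 1),   # heading: up
       L = c(0, 1, 0),   # left
       U = c(-1, 0, 0))  # H x L
}

turtle_rotate <- function(st, axis_name, ang) {
  ax <- st[[axis_name]]
  for (nm in c("H", "L", "U")) st[[nm]] <- rotate_about(st[[nm]], ax, ang)
  # guard frame orthonormality; re-orthonormalize on drift
  err <- max(abs(c(sum(st$H * st$H) - 1, sum(st$L * st$L) - 1,
                   sum(st$U * st$U) - 1, sum(st$H * st$L),
                   sum(st$H * st$U), sum(st$L * st$U))))
  if (err > 1e-9) {
    st$H <- st$H / sqrt(sum(st$H^2))
    st$L <- st$L - sum(st$L * st$H) * st$H
    st$L <- st$L / sqrt(sum(st$L^2))
    st$U <- pracma_cross(st$H, st$L)
  }
  st
}

#' Turtle interpretation settings
#'
#' @param default_radius Radius used for `F` segments without explicit radii,
#'   model units.
#' @param plastochron Duration of one plastochron in simulation time units;
#'   leaf ages carried by `L`/`P` modules are divided by
#'   `plastochron * maturation_plastochrons` to obtain normalized age.
#' @return A list of settings for [interpret()].
#' @export
turtle_config <- function(default_radius = 0.01, plastochron = 1) {
  list(default_radius = default_radius, plastochron = plastochron)
}

#' Interpret an L-string as a 3D scene
#'
#' Standard bracketed turtle interpretation. The turtle starts at the origin
#' heading straight up (+z) with a right-handed orthonormal frame (heading,
#' left, up). Symbols:
#' \describe{
#'   \item{`F(l[, r0, r1])`}{draw a (tapered) cylinder of length `l` along
#'     the heading and move; organ tag `"segment"`.}
#'   \item{`I(l, n)`}{internode cylinder at node `n`; moves the turtle.}
#'   \item{`+(a)`, `-(a)`}{turn about the up axis by ±`a` degrees.}
#'   \item{`&(a)`, `^(a)`}{pitch about the left axis by ±`a` degrees.}
#'   \item{`/(a)`, `\\(a)`}{roll about the heading by ±`a` degrees.}
#'   \item{`[`, `]`}{push / pop the turtle state (branching).}
#'   \item{`P(n, age, x_mult)`}{petiole of leaf `n`: a cylinder of constant
#'     width whose length is `petiole_length_fraction` times the current
#'     blade length; moves the turtle.}
#'   \item{`L(n, age, x_mult)`}{leaf blade of leaf `n`: emits a flat blade
#'     surface primitive placed at the current frame, with current length
#'     from the growth functions and the blade contour as width profile.}
#' }
#' Leaf ages are simulation times since emission; they are normalized by the
#' maturation duration and clamped to \[0, 1\] before evaluating the
#' elongation curve.
#'
#' @param s An [lstring()].
#' @param fs A [growth_function_set()] (used by `P`/`L` modules).
#' @param config A [turtle_config()].
#' @return An object of class `scene`: a list of geometry primitives, each
#'   tagged with its organ (`internode`, `petiole`, `blade`, `segment`) and
#'   node index.
#' @export
interpret <- function(s, fs = default_function_set(), config = turtle_config()) {
  stopifnot(inherits(s, "lstring"))
  st <- new_turtle()
  stack <- list()
  prims <- list()
  np <- 0L
  add <- function(p) {
    np <<- np + 1L
    prims[[np]] <<- p
  }
  mature_time <- fs$maturation_plastochrons * config$plastochron
  rel_age <- function(age) min(max(age / mature_time, 0), 1)

  for (m in unclass(s)) {
    sym <- m$sym; p <- m$params
    if (sym == "F" || sym == "I") {
      len <- p[1]
      r0 <- if (sym == "F" && length(p) >= 2) p[2] else config$default_radius
      r1 <- if (sym == "F" && length(p) >= 3) p[3] else r0
      tip <- st$pos + st$H * len
      add(list(type = "cylinder",
               organ = if (sym == "I") "internode" else "segment",
               node = if (sym == "I" && length(p) >= 2) p[2] else NA_real_,
               base = st$pos, tip = tip, r_base = r0, r_tip = r1))
      st$pos <- tip
    } else if (sym == "P") {
      n <- p[1]; t <- rel_age(p[2]); xm <- p[3]
      len <- fs$petiole_length_fraction * leaf_length(fs, n, t, xm)
      tip <- st$pos + st$H * len
      add(list(type = "cylinder", organ = "petiole", node = n,
               base = st$pos, tip = tip,
               r_base = fs$petiole_width / 2, r_tip = fs$petiole_width / 2))
      st$pos <- tip
    } else if (sym == "L") {
      n <- p[1]; t <- rel_age(p[2]); xm <- p[3]
      add(list(type = "blade", organ = "blade", node = n,
               origin = st$pos,
               frame = cbind(H = st$H, L = st$L, U = st$U),
               length = leaf_length(fs, n, t, xm),
               final_length = leaf_length(fs, n, 1, xm),
               rel_age = t, x_mult = xm))
    } else if (sym == "+") { st <- turtle_rotate(st, "U", p[1])
    } else if (sym == "-") { st <- turtle_rotate(st, "U", -p[1])
    } else if (sym == "&") { st <- turtle_rotate(st, "L", p[1])
    } else if (sym == "^") { st <- turtle_rotate(st, "L", -p[1])
    } else if (sym == "/") { st <- turtle_rotate(st, "H", p[1])
    } else if (sym == "\\") { st <- turtle_rotate(st, "H", -p[1])
    } else if (sym == "[") {
      stack[[length(stack) + 1L]] <- st
    } else if (sym == "]") {
      if (length(stack) == 0L)
        stop("turtle interpretation: pop of empty stack", call. = FALSE)
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    }
    # unknown symbols (e.g. apices) have no geometric interpretation
  }
  structure(list(primitives = prims[seq_len(np)]), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  organs <- vapply(x$primitives, `[[`, "", "organ")
  cat(sprintf("<scene: %d primitives (%s)>\n", length(x$primitives),
              paste(sprintf("%s: %d", names(table(organs)), table(organs)),
                    collapse = ", ")))
  invisible(x)
}

#' Count scene primitives by organ
#'
#' @param scene A `scene`.
#' @param organ Organ tag (`"blade"`, `"petiole"`, `"internode"`,
#'   `"segment"`) or `NULL` for all.
#' @return Integer count.
#' @export
scene_count <- function(scene, organ = NULL) {
  stopifnot(inherits(scene, "scene"))
  if (is.null(organ)) return(length(scene$primitives))
  sum(vapply(scene$primitives, `[[`, "", "organ") == organ)
}
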