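#' Stochastic configuration of the rosette model
#'
#' Specimen-to-specimen diversity enters the model through three random
#' quantities: a per-leaf final-size multiplier X_n ~ Normal(1, 0.01)
#' (truncated at zero), the divergence angle between consecutive leaves
#' theta_n ~ Normal(137.5, 2.5) degrees, and a uniformly random development
#' time realized as a uniform integer leaf count in \[5, 20\].
#'
#' @param x_mu,x_sigma Mean and sd of the size multipliers (unitless).
#' @param theta_mu,theta_sigma Mean and sd of the divergence angle, degrees.
#' @param leaf_count_range Inclusive integer interval of final leaf counts.
#' @param inclination_sigma Optional sd (degrees) of per-leaf jitter added to
#'   the inclination angle; 0 disables it (the default: only sizes and
#'   divergence angles are randomized).
#' @return An object of class `stochastic_config`.
#' @export
stochastic_config <- function(x_mu = 1, x_sigma = 1e-2,
                              theta_mu = 137.5, theta_sigma = 2.5,
                              leaf_count_range = c(5L, 20L),
                              inclination_sigma = 0) {
  stopifnot(x_sigma >= 0, theta_sigma >= 0, inclination_sigma >= 0,
            length(leaf_count_range) == 2,
            leaf_count_range[1] >= 1,
            leaf_count_range[2] >= leaf_count_range[1])
  structure(list(x_mu = x_mu, x_sigma = x_sigma,
                 theta_mu = theta_mu, theta_sigma = theta_sigma,
                 leaf_count_range = as.integer(leaf_count_range),
                 inclination_sigma = inclination_sigma),
            class = "stochastic_config")
}

#' Sample parameters for one simulated plant
#'
#' Draws the stochastic state of a single rosette: the target leaf count
#' (uniform over the configured integer range), one size multiplier per leaf
#' (normal, truncated at zero), and one divergence angle per leaf (normal).
#'
#' @param cfg A [stochastic_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `rosette_params` with fields
#'   `target_leaf_count`, `x_mult`, `theta`, `inclination_jitter`, `seed`.
#' @export
sample_rosette_params <- function(cfg = stochastic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "stochastic_config"))
  if (!is.null(seed)) set.seed(seed)
  lo <- cfg$leaf_count_range[1]; hi <- cfg$leaf_count_range[2]
  n <- as.integer(sample.int(hi - lo + 1L, 1L) + lo - 1L)
  x <- stats::rnorm(n, cfg$x_mu, cfg$x_sigma)
  while (any(x <= 0)) { # truncation at 0; essentially never triggers
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), cfg$x_mu, cfg$x_sigma)
  }
  th <- stats::rnorm(n, cfg$theta_mu, cfg$theta_sigma)
  ij <- if (cfg$inclination_sigma > 0)
    stats::rnorm(n, 0, cfg$inclination_sigma) else rep(0, n)
  structure(list(target_leaf_count = n, x_mult = x, theta = th,
                 inclination_jitter = ij,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "rosette_params")
}

#' @export
print.rosette_params <- function(x, ...) {
  cat(sprintf("<rosette_params: %d leaves, mean divergence %.1f deg>\n",
              x$target_leaf_count, mean(x$theta)))
  invisible(x)
}

#' Save / load rosette parameters
#'
#' Plain-text (YAML) provenance record for a single simulated plant, written
#' at full double precision so a replayed build is bit-identical.
#'
#' @param params A `rosette_params` object.
#' @param path File path.
#' @export
save_rosette_params <- function(params, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = ", ")
  txt <- c(sprintf("target_leaf_count: %d", params$target_leaf_count),
           sprintf("x_mult: [%s]", num(params$x_mult)),
           sprintf("theta: [%s]", num(params$theta)),
           sprintf("inclination_jitter: [%s]", num(params$inclination_jitter)),
           sprintf("seed: %s", ifelse(is.na(params$seed), "~", params$seed)))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname save_rosette_params
#' @export
load_rosette_params <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(target_leaf_count = as.integer(y$target_leaf_count),
                 x_mult = as.numeric(y$x_mult),
                 theta = as.numeric(y$theta),
                 inclination_jitter = as.numeric(y$inclination_jitter),
                 seed = if (is.null(y$seed)) NA_integer_ else as.integer(y$seed)),
            class = "rosette_params")
}

#' The rosette grammar
#'
#' Builds the axiom and production of the monopodial rosette: an apex
#' `A(n, timer)` that, once its timer crosses a plastochron, emits a short
#' internode, rolls the stem frame by the drawn divergence angle, and
#' branches off a leaf (pitch by the node's inclination angle, petiole,
#' blade), becoming `A(n + 1, timer - plastochron)`. Emission stops after
#' `target_leaf_count` leaves; existing leaves keep aging.
#'
#' @param params A `rosette_params` (see [sample_rosette_params()]).
#' @param fs A [growth_function_set()].
#' @param plastochron Plastochron duration, simulation time units.
#' @param internode_length Internode length, model units (the "short stem").
#' @return A list with `axiom`, `productions`, `age_params`.
#' @export
rosette_grammar <- function(params, fs, plastochron = 1,
                            internode_length = 0.01) {
  stopifnot(inherits(params, "rosette_params"),
            inherits(fs, "growth_function_set"))
  eps <- 1e-9
  target <- params$target_leaf_count
  apex <- production(
    "A", name = "apex-emission",
    condition = function(p, clock) p[2] >= plastochron - eps && p[1] <= target,
    successor = function(p, clock) {
      n <- p[1]
      ang <- eval_curve(fs$f_ang, n / fs$max_node) + params$inclination_jitter[n]
      list(lmod("I", internode_length, n),
           lmod("/", params$theta[n]),
           lmod("["),
           lmod("&", ang),
           lmod("P", n, 0, params$x_mult[n]),
           lmod("L", n, 0, params$x_mult[n]),
           lmod("]"),
           lmod("A", n + 1, p[2] - plastochron))
    })
  list(axiom = lstring(list(lmod("A", 1, 0))),
       productions = list(apex),
       age_params = c(A = 2L, L = 2L, P = 2L))
}

#' Build one rosette
#'
#' Runs the rosette grammar for exactly `target_leaf_count` plastochrons
#' plus a post-emission growth tail (so the youngest leaves are small but
#' present), then interprets the resulting string as 3D geometry. The
#' returned leaf-count label is the number of blade primitives in the scene,
#' which by construction equals `params$target_leaf_count` — ground truth is
#' exact and independent of rendering. Deterministic: identical
#' `(params, fs)` give a bit-identical scene.
#'
#' @param params A `rosette_params`.
#' @param fs A [growth_function_set()].
#' @param dt Derivation time step (default plastochron / 10).
#' @param plastochron Plastochron duration (default 1 time unit).
#' @param tail_plastochrons Growth time after the last emission, in
#'   plastochrons (default 2).
#' @param internode_length Internode length, model units.
#' @return A list with `scene` (a `scene`), `leaf_count` (integer label),
#'   `string` (the final [lstring()]).
#' @export
build_rosette <- function(params, fs = default_function_set(),
                          dt = 0.1, plastochron = 1,
                          tail_plastochrons = 2,
                          internode_length = 0.01) {
  g <- rosette_grammar(params, fs, plastochron, internode_length)
  total_time <- (params$target_leaf_count + tail_plastochrons) * plastochron
  n_steps <- as.integer(round(total_time / dt))
  s <- derive(g$axiom, g$productions, dt, n_steps, age_params = g$age_params)
  scene <- interpret(s, fs, turtle_config(plastochron = plastochron))
  list(scene = scene,
       leaf_count = scene_count(scene, "blade"),
       string = s)
}
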