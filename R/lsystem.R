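#' Parametric L-system modules and strings
#'
#' A module is a symbol plus an ordered vector of real parameters; an
#' L-string is a sequence of modules, including the branch brackets `[` and
#' `]` (modules with no parameters). Productions rewrite modules in parallel
#' at each derivation step.
#'
#' @param sym Module symbol (non-empty string, e.g. `"A"`, `"F"`, `"["`).
#' @param ... Numeric parameters.
#' @return `lmod` returns a module; `lstring` an object of class `lstring`.
#' @export
lmod <- function(sym, ...) {
  if (!nzchar(sym)) stop("module symbol must be non-empty", call. = FALSE)
  list(sym = sym, params = as.numeric(c(...)))
}

#' @rdname lmod
#' @param mods A list of modules.
#' @export
lstring <- function(mods = list()) {
  depth <- 0L
  for (m in mods) {
    if (m$sym == "[") depth <- depth + 1L
    if (m$sym == "]") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced brackets in L-string", call. = FALSE)
    }
  }
  if (depth != 0L) stop("unbalanced brackets in L-string", call. = FALSE)
  structure(mods, class = "lstring")
}

#' @export
print.lstring <- function(x, ...) {
  cat(format_lstring(x), "\n")
  invisible(x)
}

#' @export
length.lstring <- function(x) length(unclass(x))

#' Text serialization of L-strings
#'
#' `format_lstring` prints a string such as `A(3) [ &(40) L(5,0.7) ] `;
#' `parse_lstring` parses it back. The round trip is exact to double
#' precision (parameters are printed with 17 significant digits).
#'
#' @param s An [lstring()].
#' @return A character scalar / an [lstring()].
#' @export
format_lstring <- function(s) {
  paste(vapply(unclass(s), function(m) {
    if (length(m$params) == 0) m$sym
    else sprintf("%s(%s)", m$sym,
                 paste(sprintf("%.17g", m$params), collapse = ","))
  }, character(1)), collapse = " ")
}

#' @rdname format_lstring
#' @param text Character scalar to parse.
#' @export
parse_lstring <- function(text) {
  toks <- regmatches(text, gregexpr(
    "[^()\\s,]+(\\([^)]*\\))?", text, perl = TRUE))[[1]]
  mods <- lapply(toks, function(tk) {
    if (grepl("\\(", tk)) {
      sym <- sub("\\(.*$", "", tk)
      inner <- sub("^.*\\(", "", sub("\\)$", "", tk))
      ps <- if (nzchar(inner)) as.numeric(strsplit(inner, ",")[[1]]) else numeric(0)
      if (anyNA(ps)) stop("unparseable parameters in module: ", tk, call. = FALSE)
      lmod(sym, ps)
    } else lmod(tk)
  })
  lstring(mods)
}

#' L-system production
#'
#' A rewriting rule: when a module with the predecessor symbol satisfies the
#' condition, it is replaced by the modules returned by the successor. The
#' condition and successor both see the module's (already age-advanced)
#' parameters and the global simulation clock; successors may draw from R's
#' random number stream, which [derive()] seeds, making derivations
#' reproducible in string order.
#'
#' @param symbol Predecessor symbol.
#' @param condition `function(params, clock)` returning `TRUE`/`FALSE`
#'   (default: always applicable).
#' @param successor `function(params, clock)` returning a list of modules
#'   (see [lmod()]). Must preserve bracket balance.
#' @param name Optional rule name used in error messages.
#' @return An object of class `production`.
#' @export
production <- function(symbol, successor,
                       condition = function(params, clock) TRUE,
                       name = symbol) {
  structure(list(symbol = symbol, condition = condition,
                 successor = successor, name = name),
            class = "production")
}

balanced <- function(mods) {
  depth <- 0L
  for (m in mods) {
    if (m$sym == "[") depth <- depth + 1L
    else if (m$sym == "]") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
  }
  depth == 0L
}

#' Derive an L-string
#'
#' Timed parallel rewriting. At every step the global clock advances by
#' `dt`; each module first has its age parameter (if its symbol appears in
#' `age_params`) advanced by `dt`, then the first matching production (same
#' symbol, condition true) replaces it. Modules with no matching production
#' persist. Productions apply in parallel (all decisions are taken against
#' the pre-step string) and left to right, so any random draws occur in
#' string order.
#'
#' @param axiom An [lstring()].
#' @param productions List of [production()] rules.
#' @param dt Time increment per step (> 0).
#' @param n_steps Number of derivation steps (>= 0); 0 returns the axiom.
#' @param age_params Named integer vector mapping symbols to the (1-based)
#'   index of their age parameter, advanced by `dt` each step.
#' @param seed Optional integer; seeds R's RNG for stochastic successors.
#' @param clock0 Initial clock value (default 0).
#' @return The derived [lstring()], with attribute `"clock"` holding the
#'   final clock value.
#' @examples
#' # an apex that emits one leaf per unit time
#' ax <- lstring(list(lmod("A", 0)))
#' rule <- production("A",
#'   condition = function(p, clock) p[1] >= 1,
#'   successor = function(p, clock) list(lmod("L", 0), lmod("A", p[1] - 1)))
#' s <- derive(ax, list(rule), dt = 0.25, n_steps = 12, age_params = c(A = 1))
#' sum(vapply(s, function(m) m$sym == "L", logical(1)))  # 3 leaves
#' @export
derive <- function(axiom, productions, dt, n_steps,
                   age_params = integer(0), seed = NULL, clock0 = 0) {
  stopifnot(inherits(axiom, "lstring"), dt > 0, n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  by_sym <- split(productions, vapply(productions, `[[`, "", "symbol"))
  s <- unclass(axiom)
  clock <- clock0
  for (step in seq_len(n_steps)) {
    clock <- clock + dt
    out <- vector("list", 4L * length(s))
    k <- 0L
    for (m in s) {
      ai <- age_params[m$sym]
      if (!is.na(ai) && length(ai) && length(m$params) >= ai)
        m$params[ai] <- m$params[ai] + dt
      repl <- NULL
      for (p in by_sym[[m$sym]] %||% list()) {
        if (isTRUE(p$condition(m$params, clock))) {
          repl <- p$successor(m$params, clock)
          if (!balanced(repl))
            stop(sprintf("production '%s' produced unbalanced brackets",
                         p$name), call. = FALSE)
          break
        }
      }
      if (is.null(repl)) repl <- list(m)
      for (r in repl) {
        k <- k + 1L
        if (k > length(out)) out <- c(out, vector("list", length(out)))
        out[[k]] <- r
      }
    }
    s <- out[seq_len(k)]
  }
  res <- lstring(s)
  attr(res, "clock") <- clock
  res
}
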