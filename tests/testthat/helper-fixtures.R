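# shared fixtures; expensive objects are generated once per session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

default_fs <- function() cached("fs", default_function_set())

# a small rendered S12-style dataset shared by dataset/CNN tests
small_s12 <- function() cached("small_s12", {
  spec <- dataset_preset("S12", n_images = 24, image_size = 48,
                         master_seed = 101)
  generate_dataset(spec, file.path(tempdir(), "fixture_s12"),
                   blade_res = c(12, 4))
})

# independent Fritsch-Carlson monotone-cubic oracle (reference formulas,
# implemented directly from the published algorithm; independent of
# stats::splinefun)
fc_oracle <- function(u, v, xq) {
  n <- length(u)
  h <- diff(u)
  delta <- diff(v) / h
  m <- numeric(n)
  m[1] <- delta[1]; m[n] <- delta[n - 1]
  if (n > 2)
    for (i in 2:(n - 1))
      m[i] <- if (delta[i - 1] * delta[i] <= 0) 0
              else (delta[i - 1] + delta[i]) / 2
  for (i in seq_len(n - 1)) {
    if (delta[i] == 0) { m[i] <- 0; m[i + 1] <- 0; next }
    a <- m[i] / delta[i]; b <- m[i + 1] / delta[i]
    s <- a^2 + b^2
    if (s > 9) {
      tau <- 3 / sqrt(s)
      m[i] <- tau * a * delta[i]
      m[i + 1] <- tau * b * delta[i]
    }
  }
  vapply(xq, function(x) {
    x <- min(max(x, u[1]), u[n])
    i <- findInterval(x, u, rightmost.closed = TRUE)
    i <- min(i, n - 1)
    t <- (x - u[i]) / h[i]
    h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2;    h11 <- t^3 - t^2
    h00 * v[i] + h10 * h[i] * m[i] + h01 * v[i + 1] + h11 * h[i] * m[i + 1]
  }, numeric(1))
}

# rotation-matrix oracle for turtle frames (degrees, Rodrigues form)
rot_matrix <- function(axis, ang) {
  th <- ang * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
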