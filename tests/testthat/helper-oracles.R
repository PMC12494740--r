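# Brute-force reference implementations used as independent oracles.
# Deliberately written as explicit loops over pixels/bins/starts, sharing
# no code with the package internals.

oracle_std <- function(vals) {
  d <- dim(vals)
  out <- numeric(d[3])
  for (l in seq_len(d[3])) {
    mu <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      mu <- mu + vals[i, j, l]
    mu <- mu / (d[1] * d[2])
    ss <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      ss <- ss + (vals[i, j, l] - mu)^2
    out[l] <- sqrt(ss / (d[1] * d[2]))
  }
  out
}

oracle_bin <- function(x, B) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  idx <- integer(length(x))
  width <- (hi - lo) / B
  for (i in seq_along(x)) {
    b <- floor((x[i] - lo) / width) + 1
    idx[i] <- min(b, B)
  }
  idx
}

oracle_entropy <- function(vals, B) {
  d <- dim(vals)
  out <- numeric(d[3])
  n <- d[1] * d[2]
  for (l in seq_len(d[3])) {
    idx <- oracle_bin(as.vector(vals[, , l]), B)
    h <- 0
    for (b in seq_len(B)) {
      p <- sum(idx == b) / n
      if (p > 0) h <- h - p * log2(p)
    }
    out[l] <- h
  }
  out
}

oracle_mi <- function(vals, B) {
  d <- dim(vals)
  n <- d[1] * d[2]
  M <- matrix(vals, n, d[3])
  mu <- numeric(n)
  for (i in seq_len(n)) mu[i] <- sum(M[i, ]) / d[3]
  u <- oracle_bin(mu, B)
  out <- numeric(d[3])
  for (l in seq_len(d[3])) {
    v <- oracle_bin(M[, l], B)
    mi <- 0
    for (a in seq_len(B)) for (b in seq_len(B)) {
      pvu <- sum(v == a & u == b) / n
      if (pvu > 0) {
        pv <- sum(v == a) / n
        pu <- sum(u == b) / n
        mi <- mi + pvu * log2(pvu / (pv * pu))
      }
    }
    out[l] <- mi
  }
  out
}

oracle_window_scores <- function(scores, w) {
  n <- length(scores)
  out <- numeric(n - w + 1)
  for (s in seq_len(n - w + 1)) out[s] <- sum(scores[s:(s + w - 1)])
  out
}

oracle_select <- function(scores, w) {
  ws <- oracle_window_scores(scores, w)
  best <- 1L
  for (s in seq_along(ws)) if (ws[s] > ws[best]) best <- s
  list(s = as.integer(best - 1L), e = as.integer(best - 1L + w),
       score = ws[best])
}

# small random cube fixture
rand_cube <- function(y = 4, x = 4, C = 8, seed = NULL, axis = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(axis)) axis <- wavelength_axis(325, 0.728, C)
  hypercube(array(runif(y * x * C), c(y, x, C)), axis)
}

# dataset fixture: tiny simulated dataset
tiny_sim <- function(n_classes = 3, cubes_per_class = 4, spatial = c(8, 8),
                     seed = 1, ...) {
  sim_config("test", n_classes = n_classes,
             cubes_per_class = cubes_per_class, spatial = spatial,
             seed = seed, ...)
}
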