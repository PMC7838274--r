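# Independent oracles used across the suite. These deliberately do not share
# code with the package implementations they check.

# Naive recursive Ramer-Douglas-Peucker, returning kept indices.
rdp_oracle <- function(x, y, epsilon, method = "vertical") {
  n <- length(x)
  if (n <= 2L) return(seq_len(n))
  dev <- function(i) {
    if (method == "vertical") {
      yhat <- y[1] + (y[n] - y[1]) * (x[i] - x[1]) / (x[n] - x[1])
      abs(y[i] - yhat)
    } else {
      dx <- x[n] - x[1]; dy <- y[n] - y[1]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) sqrt((x[i] - x[1])^2 + (y[i] - y[1])^2)
      else abs(dy * x[i] - dx * y[i] + x[n] * y[1] - y[n] * x[1]) / len
    }
  }
  ds <- vapply(2:(n - 1), dev, numeric(1))
  if (max(ds) > epsilon) {
    split <- which.max(ds) + 1L
    left <- rdp_oracle(x[1:split], y[1:split], epsilon, method)
    right <- rdp_oracle(x[split:n], y[split:n], epsilon, method) + split - 1L
    union(left, right)
  } else {
    c(1L, n)
  }
}

# Two-sided Fisher exact p by direct hypergeometric enumeration
# (point-probability rule).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Exhaustive PAM objective for k = 2 under L1 distance.
pam2_oracle_objective <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x, method = "manhattan"))
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    obj <- sum(pmin(d[, i], d[, j]))
    if (obj < best) best <- obj
  }
  best
}

# A small co-recorded culture of processed residual traces for synchrony
# tests, built without the generator.
toy_residuals <- function(n = 500, n_cells = 4, rho_source = NULL, seed = 1) {
  set.seed(seed)
  src <- rho_source %||% rnorm(n)
  lapply(seq_len(n_cells), function(i) 0.5 * src + rnorm(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
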