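# Independent oracles and small fixture builders shared across test files.

# brute-force bit-level decoder for PLINK bed (independent of the reader)
bruteBedDecode <- function(path, n, m) {
  raw <- readBin(path, "raw", n = 3 + m * ceiling(n / 4))
  stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b))
  body <- raw[-(1:3)]
  bpm <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      byte <- as.integer(body[(j - 1) * bpm + (i - 1) %/% 4 + 1])
      two <- (byte %/% 4^((i - 1) %% 4)) %% 4
      out[i, j] <- switch(two + 1L, 2L, NA_integer_, 1L, 0L)
    }
  }
  out
}

# naive O(n^2 m) additive GRM
bruteAdditiveGRM <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X)
  W <- sweep(X, 2, 2 * p)
  norm <- sum(2 * p * (1 - p))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- sum(W[i, ] * W[j, ]) / norm
  A
}

# naive O(n^2 m) dominance GRM
bruteDominanceGRM <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  q <- 1 - p
  n <- nrow(X)
  W <- matrix(0, n, ncol(X))
  for (k in seq_len(ncol(X)))
    W[, k] <- c(-2 * p[k]^2, 2 * p[k] * q[k], -2 * q[k]^2)[X[, k] + 1]
  norm <- sum((2 * p * q)^2)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(W[i, ] * W[j, ]) / norm
  D
}

# dense GLS oracle: (X' V^-1 X)^-1 X' V^-1 y with explicit inverse
denseGls <- function(y, X, V) {
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  b <- C %*% t(X) %*% Vi %*% y
  n <- length(y)
  r <- qr(X)$rank
  s2 <- drop(t(y - X %*% b) %*% Vi %*% (y - X %*% b)) / (n - r)
  list(beta = drop(b), cov = C * s2, df = n - r, s2 = s2)
}

# tiny deterministic genotype panel
toyGeno <- function(n = 6, m = 4, seed = 42) {
  set.seed(seed)
  codes <- matrix(sample(0:2, n * m, TRUE), n, m)
  info <- data.frame(chr = rep(1, m), pos = seq_len(m) * 100,
                     id = paste0("s", seq_len(m)), ref = "A", alt = "B")
  GenotypeData(codes, info, indIds = paste0("I", seq_len(n)))
}

# shared mid-size simulated dataset (built once per test run)
.fixtureEnv <- new.env()
sharedSim <- function() {
  if (is.null(.fixtureEnv$sim)) {
    cfg <- simConfig(nSires = 25, nLitters = 160, litterSize = c(2, 3),
                     nSnps = 600, nChromosomes = 5, nQtl = 60, seed = 11)
    .fixtureEnv$sim <- c(simulateDataset(cfg, keepFounders = TRUE),
                         list(config = cfg))
  }
  .fixtureEnv$sim
}
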