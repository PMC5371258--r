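# small additive-only dataset used by several blocks
.gremlToy <- function(n = 40, m = 120, h2 = 0.5, seed = 13) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep]; p <- p[keep]
  W <- sweep(X, 2, 2 * p)
  a <- drop(W %*% rnorm(ncol(W))) ; a <- a * sqrt(h2 / var(a))
  e <- rnorm(n); e <- e * sqrt((1 - h2) / var(e))
  y <- 5 + a + e
  rownames(X) <- paste0("I", seq_len(n))
  list(y = y, X = X, A = additiveGRM(X), a = a)
}

test_that("REML maximum agrees with a direct likelihood grid search", {
  toy <- .gremlToy(n = 40)
  spec <- mixedModelSpec(toy$y, A = toy$A)
  vc <- fitGreml(spec)
  grid <- seq(0.02, 2, length.out = 50)
  ll <- outer(grid, grid, Vectorize(function(sa, se)
    remlLogLik(spec, c(sa, se))))
  best <- which(ll == max(ll), arr.ind = TRUE)
  cell <- diff(grid)[1]
  expect_lt(abs(vc@sigma[["additive"]] - grid[best[1]]), cell)
  expect_lt(abs(vc@sigma[["residual"]] - grid[best[2]]), cell)
  expect_gte(vc@logLik, max(ll) - 1e-6)
})

test_that("permuted phenotypes yield near-zero heritability", {
  hits <- vapply(1:20, function(s) {
    toy <- .gremlToy(n = 600, m = 150, h2 = 0.4, seed = 500 + s)
    set.seed(1000 + s)
    spec <- mixedModelSpec(sample(toy$y), A = toy$A)
    h2values(heritabilities(fitGreml(spec)))[["additive"]] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("REML is shift-invariant and scale-equivariant", {
  toy <- .gremlToy(n = 60, m = 100, seed = 17)
  vc1 <- fitGreml(mixedModelSpec(toy$y, A = toy$A))
  vc2 <- fitGreml(mixedModelSpec(toy$y + 100, A = toy$A))
  expect_equal(vc1@sigma, vc2@sigma, tolerance = 1e-5)
  vc3 <- fitGreml(mixedModelSpec(3 * toy$y, A = toy$A))
  expect_equal(9 * vc1@sigma, vc3@sigma, tolerance = 1e-4)
  # heritabilities are scale-free
  expect_equal(h2values(heritabilities(vc1)), h2values(heritabilities(vc3)),
               tolerance = 1e-4)
})

test_that("heritability ratios and the broad-sense sum are exact", {
  vc <- new("VarianceComponents",
            sigma = c(additive = 0.365, dominance = 0.035, residual = 0.600),
            se = c(0.03, 0.02, 0.03), aiInv = diag(3) * 1e-4,
            logLik = 0, iterations = 1L, converged = TRUE,
            boundary = rep(FALSE, 3), n = 100L)
  h2 <- h2values(heritabilities(vc))
  expect_equal(h2[["additive"]], 0.365)
  expect_equal(h2[["dominance"]], 0.035)
  expect_equal(h2[["total"]], 0.400)
  # all-residual edge and scale invariance
  vc0 <- new("VarianceComponents",
             sigma = c(additive = 0, dominance = 0, residual = 1),
             se = rep(0, 3), aiInv = diag(3), logLik = 0, iterations = 1L,
             converged = TRUE, boundary = rep(FALSE, 3), n = 100L)
  expect_equal(unname(h2values(heritabilities(vc0))), c(0, 0, 0))
  vc2 <- vc; vc2@sigma <- 2 * vc@sigma
  expect_equal(h2values(heritabilities(vc2)), h2)
})

test_that("GREML on a family model agrees with lme4", {
  skip_if_not_installed("lme4")
  set.seed(19)
  fam <- factor(rep(1:40, each = 5))
  u <- rnorm(40, 0, sqrt(0.3))
  y <- 2 + u[fam] + rnorm(200, 0, sqrt(0.7))
  Z <- stats::model.matrix(~ fam - 1)
  vc <- fitGreml(mixedModelSpec(y, A = tcrossprod(Z)))
  lf <- lme4::lmer(y ~ (1 | fam), REML = TRUE)
  vl <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(vc@sigma[["additive"]], vl[1], tolerance = 1e-4)
  expect_equal(vc@sigma[["residual"]], vl[2], tolerance = 1e-4)
})

test_that("GBLUP interpolates phenotypes as residual variance vanishes", {
  toy <- .gremlToy(n = 30, m = 80, seed = 23)
  spec <- mixedModelSpec(toy$y, A = toy$A)
  vc <- new("VarianceComponents",
            sigma = c(additive = var(toy$y), residual = 1e-9 * var(toy$y)),
            se = c(0, 0), aiInv = diag(2), logLik = 0, iterations = 1L,
            converged = TRUE, boundary = rep(FALSE, 2), n = 30L)
  gb <- gblup(spec, vc)
  resid <- toy$y - gb@fixef[["(Intercept)"]]
  expect_equal(gb@pred$gHat, resid, tolerance = 1e-4)
})

test_that("GBLUP solutions match Henderson's mixed-model equations", {
  set.seed(29)
  toy <- .gremlToy(n = 30, m = 90, seed = 29)
  batch <- sample(c("a", "b", "c"), 30, TRUE)
  spec <- mixedModelSpec(toy$y, A = toy$A, batch = batch)
  vc <- fitGreml(spec)
  gb <- gblup(spec, vc)
  # independent dense solve of [X'X  X'Z; Z'X  Z'Z + A^-1 k] with Z = I
  sa <- vc@sigma[["additive"]]; se2 <- vc@sigma[["residual"]]
  X <- spec@X
  Ai <- solve(spec@A + diag(30) * 1e-10)
  k <- se2 / sa
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(30) + Ai * k))
  rhs <- c(crossprod(X, spec@y), spec@y)
  sol <- solve(lhs, rhs)
  expect_equal(unname(gb@fixef), unname(sol[seq_len(ncol(X))]),
               tolerance = 1e-6)
  expect_equal(gb@pred$aHat, unname(sol[-seq_len(ncol(X))]),
               tolerance = 1e-6)
})

test_that("masking leaves training equations unchanged and reliabilities bounded", {
  toy <- .gremlToy(n = 50, m = 120, seed = 31)
  spec <- mixedModelSpec(toy$y, A = toy$A)
  vc <- fitGreml(spec)
  gbAll <- gblup(spec, vc)
  expect_true(all(gbAll@pred$relA >= 0 & gbAll@pred$relA <= 1))
  gbMask <- gblup(spec, vc, mask = 41:50)
  expect_true(all(gbMask@pred$masked[41:50]))
  # masked individuals have lower reliability than when phenotyped
  expect_lt(mean(gbMask@pred$relA[41:50]), mean(gbAll@pred$relA[41:50]))
  expect_error(gblup(spec, vc, mask = "nobody"), "unknown")
})

test_that("back-solved SNP effects reconstruct the breeding values", {
  set.seed(71)
  n <- 500; m <- 150
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  colnames(X) <- paste0("s", seq_len(m)); rownames(X) <- paste0("I", 1:n)
  p <- colMeans(X) / 2
  a <- drop(sweep(X, 2, 2 * p) %*% rnorm(m)); a <- a * sqrt(0.4 / var(a))
  y <- a + rnorm(n, 0, sqrt(0.6))
  ge <- GenotypeData(X, data.frame(chr = 1, pos = 1:m * 10,
                                   id = colnames(X)))
  spec <- mixedModelSpec(y, A = additiveGRM(ge), ids = indIds(ge))
  vc <- fitGreml(spec)
  gb <- gblup(spec, vc)
  eff <- suppressWarnings(backsolveSnpEffects(ge, vc, gb))
  W <- sweep(imputedCodes(ge), 2, 2 * p)
  expect_equal(drop(W %*% eff$alphaHat), gb@pred$aHat, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(sum(eff$h2Add), 1)
  # on an unlinked panel the per-SNP heritabilities sum to about the total
  h2 <- h2values(heritabilities(vc))[["additive"]]
  expect_lt(abs(sum(eff$h2Add) - h2) / h2, 0.10)
})

test_that("a simulated major QTL carries the top per-SNP heritability", {
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    n <- 250; m <- 120
    X <- matrix(rbinom(n * m, 2, 0.4), n, m)
    qtl <- 37
    y <- X[, qtl] * 0.9 + rnorm(n)
    colnames(X) <- paste0("q", 1:m)
    rownames(X) <- paste0("I", 1:n)
    ge <- GenotypeData(X, data.frame(chr = 1, pos = 1:m * 10,
                                     id = colnames(X)))
    spec <- mixedModelSpec(y, A = additiveGRM(ge), ids = indIds(ge))
    vc <- fitGreml(spec)
    eff <- backsolveSnpEffects(ge, vc, gblup(spec, vc))
    eff$id[which.max(eff$h2Add)] == "q37"
  }, TRUE)
  expect_gte(sum(hits), 9)
})
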