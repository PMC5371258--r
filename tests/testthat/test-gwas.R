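# toy scan dataset with families
.scanToy <- function(n = 60, m = 8, nFam = 3, seed = 37) {
  set.seed(seed)
  fam <- factor(rep(seq_len(nFam), length.out = n))
  codes <- matrix(rbinom(n * m, 2, 0.4), n, m)
  colnames(codes) <- paste0("s", seq_len(m))
  rownames(codes) <- paste0("I", seq_len(n))
  ge <- GenotypeData(codes, data.frame(chr = 1, pos = seq_len(m) * 100,
                                       id = colnames(codes)))
  y <- 3 + codes[, 2] * 0.5 + rnorm(n)
  list(ge = ge, y = y, fam = fam)
}

test_that("GLS scan statistics match a dense V^-1 oracle", {
  toy <- .scanToy()
  res <- glsFamilyScan(toy$ge, toy$y, family = toy$fam)
  tab <- scanTable(res)
  sf <- attr(tab, "sigmaF"); se2 <- attr(tab, "sigmaE")
  Z <- stats::model.matrix(~ toy$fam - 1)
  V <- tcrossprod(Z) * sf + diag(60) * se2
  for (k in c(1, 2, 5)) {
    x <- genoCodes(toy$ge)[, k]
    X <- cbind(1, as.numeric(x == 1), as.numeric(x == 2))
    o <- denseGls(toy$y, X, V)
    aO <- o$beta[3] / 2
    dO <- o$beta[2] - o$beta[3] / 2
    ca <- c(0, 0, 0.5); cd <- c(0, 1, -0.5)
    tA <- aO / sqrt(drop(t(ca) %*% o$cov %*% ca))
    tD <- dO / sqrt(drop(t(cd) %*% o$cov %*% cd))
    expect_equal(tab$aEst[k], aO, tolerance = 1e-10)
    expect_equal(tab$dEst[k], dO, tolerance = 1e-10)
    expect_equal(tab$tAdd[k], tA, tolerance = 1e-10)
    expect_equal(tab$tDom[k], tD, tolerance = 1e-10)
    expect_equal(tab$pAdd[k], 2 * pt(abs(tA), o$df, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("LS scan coefficients match the normal-equations oracle", {
  set.seed(41)
  n <- 50; m <- 6
  codes <- matrix(rbinom(n * m, 2, 0.3), n, m)
  colnames(codes) <- paste0("s", 1:m); rownames(codes) <- paste0("I", 1:n)
  ge <- GenotypeData(codes, data.frame(chr = 1, pos = 1:m * 10,
                                       id = colnames(codes)))
  covs <- matrix(rnorm(n * 3), n, 3)
  y <- 1 + covs %*% c(.3, -.2, .1) + codes[, 4] * 0.4 + rnorm(n)
  res <- lsMdsScan(ge, drop(y), mds = covs, nMds = 3)
  tab <- scanTable(res)
  for (k in c(1, 4, 6)) {
    X <- cbind(1, covs, codes[, k])
    b <- solve(crossprod(X), crossprod(X, y))
    r <- y - X %*% b
    s2 <- sum(r^2) / (n - ncol(X))
    seB <- sqrt(s2 * solve(crossprod(X))[5, 5])
    expect_equal(tab$aEst[k], b[5], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(tab$tAdd[k], drop(b[5] / seB), tolerance = 1e-10)
  }
  # nMds = 0 equals plain covariate-free regression
  res0 <- lsMdsScan(ge, drop(y), nMds = 0)
  X <- cbind(1, codes[, 4])
  b <- solve(crossprod(X), crossprod(X, y))
  expect_equal(scanTable(res0)$aEst[4], b[2], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("GLS reduces to LS when the family variance vanishes", {
  # families of size 1 force sigma_f to the boundary
  toy <- .scanToy(n = 40, m = 5, nFam = 40, seed = 43)
  gls <- scanTable(glsFamilyScan(toy$ge, toy$y, family = factor(1:40)))
  ls <- scanTable(lsMdsScan(toy$ge, toy$y, nMds = 0, genotypic = TRUE))
  expect_equal(gls$tAdd, ls$tAdd, tolerance = 1e-5)
  expect_equal(gls$tDom, ls$tDom, tolerance = 1e-5)
  expect_equal(gls$pAdd, ls$pAdd, tolerance = 1e-5)
})

test_that("allele flips negate the additive contrast and keep p-values", {
  toy <- .scanToy(n = 80, m = 6, seed = 47)
  flipped <- 2L - genoCodes(toy$ge)
  geF <- GenotypeData(flipped, snpInfo(toy$ge))
  r1 <- scanTable(glsFamilyScan(toy$ge, toy$y, family = toy$fam))
  r2 <- scanTable(glsFamilyScan(geF, toy$y, family = toy$fam))
  ok <- !is.na(r1$tAdd)
  expect_equal(r1$aEst[ok], -r2$aEst[ok], tolerance = 1e-8)
  expect_equal(r1$dEst[ok], r2$dEst[ok], tolerance = 1e-8)
  expect_equal(r1$pAdd[ok], r2$pAdd[ok], tolerance = 1e-8)
  expect_equal(r1$pDom[ok], r2$pDom[ok], tolerance = 1e-8)
})

test_that("sparse genotype classes fall back to the additive fit", {
  set.seed(53)
  n <- 60
  x <- c(rep(0L, 57), rep(1L, 3))          # 3 hets, no alt homozygotes
  codes <- cbind(x, rbinom(n, 2, 0.5))
  colnames(codes) <- c("rare", "common")
  rownames(codes) <- paste0("I", 1:n)
  ge <- GenotypeData(codes, data.frame(chr = 1, pos = c(10, 20),
                                       id = colnames(codes)))
  res <- scanTable(glsFamilyScan(ge, rnorm(n), family = factor(rep(1:20, 3))))
  expect_equal(res$flag[res$snp == "rare"], "additive_only")
  expect_true(is.na(res$pDom[res$snp == "rare"]))
  expect_false(is.na(res$pAdd[res$snp == "rare"]))
})

test_that("inflation factor is calibrated and equivariant", {
  set.seed(59)
  lam <- inflationFactor(rchisq(1e5, 1), squared = TRUE)
  expect_gt(lam, 0.98); expect_lt(lam, 1.02)
  t <- rnorm(5000)
  expect_equal(inflationFactor(t * sqrt(2)), 2 * inflationFactor(t),
               tolerance = 1e-10)
  expect_warning(l1 <- inflationFactor(sqrt(0.4549364)), "unstable")
  expect_equal(l1, 0.4549364 / qchisq(0.5, 1), tolerance = 1e-6)
})

test_that("Bonferroni thresholds reproduce the genome-wide cutoff", {
  expect_equal(round(bonferroniThreshold(41108, 0.05)$log10, 2), 5.91)
  expect_equal(bonferroniThreshold(1, 0.05)$threshold, 0.05)
  expect_equal(bonferroniThreshold(100, 0.05)$threshold, 5e-4)
  expect_error(bonferroniThreshold(0), "m >= 1")
})

test_that("significant-SNP sets combine with correct overlaps", {
  mk <- function(p, method) {
    tab <- data.frame(snp = paste0("s", seq_along(p)), chr = 1,
                      pos = seq_along(p), maf = 0.3, aEst = 0, dEst = 0,
                      tAdd = 0, pAdd = p, tDom = NA, pDom = NA, flag = "")
    new("ScanResult", table = tab, method = method, lambda = 1,
        threshold = 0.01)
  }
  r1 <- mk(c(.001, .002, .5, .5), "m1")
  r2 <- mk(c(.5, .5, .003, .5), "m2")
  sig <- significantSnps(list(r1, r2), threshold = 0.01)
  expect_setequal(sig$union, c("s1", "s2", "s3"))
  expect_equal(sig$overlap["m1", "m2"], 0)
  expect_equal(sig$overlap["m1", "m1"], 2)
  sigOne <- significantSnps(list(r1), threshold = 0.01)
  expect_setequal(sigOne$union, c("s1", "s2"))
})

test_that("stronger simulated QTL reach smaller p-values", {
  set.seed(61)
  n <- 1500; m <- 50
  codes <- matrix(rbinom(n * m, 2, 0.4), n, m)
  colnames(codes) <- paste0("q", 1:m); rownames(codes) <- paste0("I", 1:n)
  ge <- GenotypeData(codes, data.frame(chr = 1, pos = 1:m * 10,
                                       id = colnames(codes)))
  eff <- seq(0.1, 0.8, length.out = m)
  y <- drop(scale(codes, scale = FALSE) %*% eff) + rnorm(n)
  tab <- suppressWarnings(scanTable(lsMdsScan(ge, y, nMds = 0)))
  expect_gt(cor(eff, -log10(tab$pAdd), method = "spearman"), 0.8)
})
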