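# shared: imputed codes + sample allele frequencies, dropping monomorphic SNPs
.codesFreq <- function(ge, requirePoly = TRUE) {
  X <- imputedCodes(ge)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (requirePoly && !any(poly)) stop("all SNPs are monomorphic")
  list(X = X[, poly, drop = FALSE], p = p[poly], keep = which(poly))
}

#' Additive genomic relationship matrix
#'
#' VanRaden-type matrix: centered allele counts \eqn{W_a[i,k] = x_{ik} -
#' 2p_k}, normalized by \eqn{\sum_k 2 p_k q_k} with allele frequencies
#' estimated from the analysis sample.  Monomorphic SNPs are dropped.
#'
#' @param ge a \linkS4class{GenotypeData} or codes matrix (individuals x
#'   SNPs).
#' @return n x n matrix with attributes \code{normalizer} (\eqn{\sum 2 p q})
#'   and \code{nSnps}.
#' @export
additiveGRM <- function(ge) {
  cf <- .codesFreq(ge)
  if (ncol(cf$X) < 1) stop("need at least 1 polymorphic SNP")
  W <- sweep(cf$X, 2, 2 * cf$p)
  norm <- sum(2 * cf$p * (1 - cf$p))
  A <- tcrossprod(W) / norm
  dimnames(A) <- list(rownames(cf$X), rownames(cf$X))
  structure(A, normalizer = norm, nSnps = ncol(cf$X))
}

# dominance-deviation incidence for a codes matrix at frequencies p
.domW <- function(X, p) {
  q <- 1 - p
  W0 <- matrix(-2 * p^2, nrow(X), length(p), byrow = TRUE)
  W1 <- matrix(2 * p * q, nrow(X), length(p), byrow = TRUE)
  W2 <- matrix(-2 * q^2, nrow(X), length(p), byrow = TRUE)
  W <- W1
  # non-integer (imputed) codes get the HWE expectation, zero
  W[X == 0] <- W0[X == 0]
  W[X == 2] <- W2[X == 2]
  W[X != 0 & X != 1 & X != 2] <- 0
  W
}

#' Dominance genomic relationship matrix
#'
#' Dominance-deviation coding \eqn{W_d = -2q_k^2, 2p_kq_k, -2p_k^2} for codes
#' 2, 1, 0, normalized by \eqn{\sum_k (2 p_k q_k)^2}.
#'
#' @inheritParams additiveGRM
#' @return n x n matrix with attributes \code{normalizer} and \code{nSnps}.
#' @export
dominanceGRM <- function(ge) {
  cf <- .codesFreq(ge)
  if (ncol(cf$X) < 1) stop("need at least 1 polymorphic SNP")
  q <- 1 - cf$p
  W <- .domW(cf$X, cf$p)
  norm <- sum((2 * cf$p * q)^2)
  D <- tcrossprod(W) / norm
  dimnames(D) <- list(rownames(cf$X), rownames(cf$X))
  structure(D, normalizer = norm, nSnps = ncol(cf$X))
}

#' Identity-by-state similarity matrix
#'
#' \eqn{S_{ij}} = mean over SNPs of \eqn{(2 - |x_{ik} - x_{jk}|)/2}, in
#' [0, 1]; missing codes are mean-imputed first.
#'
#' @inheritParams additiveGRM
#' @return n x n similarity matrix.
#' @export
ibsMatrix <- function(ge) {
  X <- imputedCodes(ge)
  m <- ncol(X)
  # sum |xi - xj| via squared differences corrected for {0,2} pairs,
  # |d| = d^2 - 2 * [d^2 = 4]; exact for integer codes
  sq <- matrix(rowSums(X^2), nrow(X), nrow(X))
  d2 <- sq + t(sq) - 2 * tcrossprod(X)
  I0 <- X == 0; I2 <- X == 2
  n02 <- tcrossprod(I0 * 1, I2 * 1)
  absSum <- d2 - 2 * (n02 + t(n02))
  S <- 1 - absSum / (2 * m)
  dimnames(S) <- list(rownames(X), rownames(X))
  S
}

#' Classical MDS stratification coordinates from a similarity matrix
#'
#' Distance is 1 - similarity; classical (Torgerson) scaling of the
#' double-centered squared-distance Gram matrix.  When fewer than \code{d}
#' eigenvalues are positive, fewer columns are returned with a warning.
#'
#' @param S symmetric similarity matrix (e.g. \code{\link{ibsMatrix}}).
#' @param d number of dimensions requested.
#' @return list with \code{coords} (n x <=d, columns centered, ordered by
#'   decreasing eigenvalue) and \code{eig} (all eigenvalues).
#' @export
mdsComponents <- function(S, d = 2) {
  stopifnot(isSymmetric(unname(S), tol = 1e-8), d < nrow(S))
  D <- 1 - S
  fit <- suppressWarnings(cmdscale(D, k = d, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < d)
    warning("only ", ncol(pts), " positive-eigenvalue dimensions available")
  list(coords = pts, eig = fit$eig)
}

#' Pairwise linkage disequilibrium by EM over unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by
#' expectation-maximization (double heterozygotes split by the current
#' coupling odds), then \eqn{D = p_{AB} - p_A p_B}, Lewontin's \eqn{D'} and
#' \eqn{r^2} are derived.  Haplotype "A"/"B" denote the counted (alt) alleles
#' at the two SNPs.
#'
#' @param ge a \linkS4class{GenotypeData} or codes matrix.
#' @param snpI,snpJ SNP ids or column indices.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param maxIter maximum EM iterations.
#' @return list(D, Dprime, r2, hapFreq, pA, pB, iterations, converged).
#' @export
pairwiseLD <- function(ge, snpI, snpJ, tol = 1e-10, maxIter = 1000) {
  X <- if (is(ge, "GenotypeData")) genoCodes(ge) else as.matrix(ge)
  ids <- if (is(ge, "GenotypeData")) snpInfo(ge)$id else colnames(X)
  ix <- if (is.character(snpI)) match(snpI, ids) else as.integer(snpI)
  jx <- if (is.character(snpJ)) match(snpJ, ids) else as.integer(snpJ)
  xi <- X[, ix]; xj <- X[, jx]
  ok <- !is.na(xi) & !is.na(xj)
  xi <- xi[ok]; xj <- xj[ok]
  pA <- mean(xi) / 2; pB <- mean(xj) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) stop("both SNPs must be polymorphic")
  n <- length(xi)
  tab <- table(factor(xi, 0:2), factor(xj, 0:2))
  # haplotype counts fully determined except for double heterozygotes
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  ndh <- tab["1", "1"]
  # fixed (phase-known) haplotype counts from the other eight cells
  cAB <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"]
  cAb <- 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"]
  caB <- 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"]
  cab <- 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    num <- f["AB"] * f["ab"]
    den <- num + f["Ab"] * f["aB"]
    w <- if (den > 0) num / den else 0.5
    fNew <- c(cAB + ndh * w, cAb + ndh * (1 - w),
              caB + ndh * (1 - w), cab + ndh * w) / (2 * n)
    names(fNew) <- names(f)
    if (max(abs(fNew - f)) < tol) { f <- fNew; converged <- TRUE; break }
    f <- fNew
  }
  if (!converged)
    stop("LD EM did not converge in ", maxIter,
         " iterations; last estimate: ",
         paste(signif(f, 4), collapse = ", "))
  pAh <- f["AB"] + f["Ab"]; pBh <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pAh * pBh)
  qAh <- 1 - pAh; qBh <- 1 - pBh
  Dmax <- if (D >= 0) min(pAh * qBh, qAh * pBh) else min(pAh * pBh, qAh * qBh)
  Dprime <- if (Dmax == 0) 0 else abs(D) / Dmax
  r2 <- if (pAh * qAh * pBh * qBh == 0) 0 else
    D^2 / unname(pAh * qAh * pBh * qBh)
  list(D = D, Dprime = unname(Dprime), r2 = r2, hapFreq = f,
       pA = unname(pAh), pB = unname(pBh), iterations = iter,
       converged = converged)
}

#' Write a GRM in GCTA text dialect (lower triangle)
#'
#' Columns: index i, index j, number of SNPs, relationship value; ids in a
#' companion \code{.grm.id} file.
#'
#' @param G relationship matrix from \code{\link{additiveGRM}} or
#'   \code{\link{dominanceGRM}}.
#' @param prefix output prefix (writes \code{<prefix>.grm.txt} and
#'   \code{<prefix>.grm.id}).
#' @export
writeGRM <- function(G, prefix) {
  n <- nrow(G)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- attr(G, "nSnps")
  if (is.null(m)) m <- NA_integer_
  df <- data.frame(i = idx[, 1], j = idx[, 2], nsnp = m,
                   value = G[idx])
  write.table(df, paste0(prefix, ".grm.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  write.table(data.frame(fid = ids, iid = ids), paste0(prefix, ".grm.id"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
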