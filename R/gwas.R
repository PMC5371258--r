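# whiten y and X by the inverse Cholesky of V (GLS -> OLS); V = NULL is OLS
.whiten <- function(y, X, V = NULL) {
  if (is.null(V)) return(list(y = y, X = X))
  L <- t(chol(V))
  list(y = forwardsolve(L, y), X = forwardsolve(L, X))
}

# core single-SNP scan: per-SNP genotype-factor (or allele-count) fit on top
# of a base design, by OLS on (optionally whitened) data
.scanEngine <- function(y, Xbase, codes, info, V = NULL, genotypic = TRUE,
                        minClass = 5, method = "scan", alpha = 0.05) {
  L <- if (is.null(V)) NULL else t(chol(V))
  w <- if (is.null(L)) list(y = y, X = Xbase)
       else list(y = forwardsolve(L, y), X = forwardsolve(L, Xbase))
  n <- length(y)
  m <- ncol(codes)
  out <- data.frame(
    snp = info$id, chr = info$chr, pos = info$pos,
    maf = NA_real_, aEst = NA_real_, dEst = NA_real_,
    tAdd = NA_real_, pAdd = NA_real_, tDom = NA_real_, pDom = NA_real_,
    flag = "", stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    x <- codes[, k]
    ok <- !is.na(x)
    cnt <- tabulate(x[ok] + 1L, 3L)
    p <- (2 * cnt[3] + cnt[2]) / (2 * sum(cnt))
    out$maf[k] <- min(p, 1 - p)
    if (p == 0 || p == 1) { out$flag[k] <- "monomorphic"; next }
    useFactor <- genotypic && all(cnt >= minClass)
    if (genotypic && !useFactor) out$flag[k] <- "additive_only"
    xin <- x
    if (anyNA(xin)) xin[is.na(xin)] <- 2 * p
    if (useFactor) {
      # genotype-class coding: columns are indicators of classes 1 and 2;
      # class means mu0 = base, mu1 = base + b1, mu2 = base + b2
      G <- cbind(as.numeric(xin == 1), as.numeric(xin == 2))
      Gw <- if (is.null(L)) G else forwardsolve(L, G)
      fit <- lm.fit(cbind(w$X, Gw), w$y)
      r <- fit$rank
      df <- n - r
      if (df < 1 || any(is.na(fit$coefficients[ncol(w$X) + 1:2]))) {
        out$flag[k] <- "rank_deficient"; next
      }
      XtX <- crossprod(cbind(w$X, Gw))
      Cinv <- tryCatch(solve(XtX), error = function(e) NULL)
      if (is.null(Cinv)) { out$flag[k] <- "rank_deficient"; next }
      s2 <- sum(fit$residuals^2) / df
      b1 <- fit$coefficients[ncol(w$X) + 1]
      b2 <- fit$coefficients[ncol(w$X) + 2]
      # additive contrast a = (mu2 - mu0)/2 = b2/2; dominance d = b1 - b2/2
      ca <- c(rep(0, ncol(w$X)), 0, 0.5)
      cd <- c(rep(0, ncol(w$X)), 1, -0.5)
      aEst <- b2 / 2
      dEst <- b1 - b2 / 2
      seA <- sqrt(s2 * drop(t(ca) %*% Cinv %*% ca))
      seD <- sqrt(s2 * drop(t(cd) %*% Cinv %*% cd))
      out$aEst[k] <- aEst; out$dEst[k] <- dEst
      out$tAdd[k] <- aEst / seA
      out$tDom[k] <- dEst / seD
      out$pAdd[k] <- 2 * pt(abs(out$tAdd[k]), df, lower.tail = FALSE)
      out$pDom[k] <- 2 * pt(abs(out$tDom[k]), df, lower.tail = FALSE)
    } else {
      xw <- if (is.null(L)) xin else forwardsolve(L, xin)
      fit <- lm.fit(cbind(w$X, xw), w$y)
      r <- fit$rank
      df <- n - r
      cidx <- ncol(w$X) + 1
      if (df < 1 || is.na(fit$coefficients[cidx])) {
        out$flag[k] <- "rank_deficient"; next
      }
      XtX <- crossprod(cbind(w$X, xw))
      Cinv <- tryCatch(solve(XtX), error = function(e) NULL)
      if (is.null(Cinv)) { out$flag[k] <- "rank_deficient"; next }
      s2 <- sum(fit$residuals^2) / df
      aEst <- fit$coefficients[cidx]
      seA <- sqrt(s2 * Cinv[cidx, cidx])
      out$aEst[k] <- aEst
      out$tAdd[k] <- aEst / seA
      out$pAdd[k] <- 2 * pt(abs(out$tAdd[k]), df, lower.tail = FALSE)
    }
  }
  tested <- !is.na(out$tAdd)
  lam <- if (sum(tested) > 0) inflationFactor(out$tAdd[tested]) else NA_real_
  thr <- bonferroniThreshold(max(sum(tested), 1), alpha)
  new("ScanResult", table = out, method = method, lambda = lam,
      threshold = thr$threshold)
}

#' Single-SNP GWAS by generalized least squares with family random effects
#'
#' Fits, for every SNP, \eqn{y = X_b b + X g + Z f + e} with a common family
#' variance (sibs in the same family are equicorrelated).  The family and
#' residual variances are estimated once by REML under the no-SNP model and
#' held fixed across SNPs; each SNP's genotype is then fitted as a 3-level
#' factor by GLS and additive/dominance contrasts of the genotype-class
#' values are tested by t tests with df = n - rank(fixed design).  Genotype
#' classes with fewer than \code{minClass} observations trigger an
#' additive-only (allele-count) fit, flagged in the output.
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param y phenotype vector aligned with \code{indIds(ge)}.
#' @param batch optional batch labels (fixed effects).
#' @param family family labels; default the \code{litter} column of
#'   \code{colData} (full sibs); set to the sire column for sire families.
#' @param minClass minimum genotype-class count for the 3-level factor fit.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return A \linkS4class{ScanResult}; \code{sigmaF}, \code{sigmaE} attached
#'   as attributes of the table.
#' @export
glsFamilyScan <- function(ge, y, batch = NULL,
                          family = SummarizedExperiment::colData(ge)$litter,
                          minClass = 5, alpha = 0.05) {
  stopifnot(length(y) == nInds(ge), !is.null(family))
  fam <- factor(family)
  Xb <- .batchDesign(length(y), batch)
  # variance components of the no-SNP family model via REML on kernel ZZ'
  Z <- stats::model.matrix(~ fam - 1)
  K <- tcrossprod(Z)
  spec <- mixedModelSpec(y, A = K, batch = batch)
  vcf <- fitGreml(spec)
  sf <- vcf@sigma[["additive"]]
  se2 <- vcf@sigma[["residual"]]
  V <- sf * K
  diag(V) <- diag(V) + se2
  res <- .scanEngine(y, Xb, genoCodes(ge), snpInfo(ge), V = V,
                     genotypic = TRUE, minClass = minClass,
                     method = "gls_family", alpha = alpha)
  attr(res@table, "sigmaF") <- sf
  attr(res@table, "sigmaE") <- se2
  res
}

.batchDesign <- function(n, batch) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(batch)) {
    b <- factor(batch)
    if (nlevels(b) > 1) X <- cbind(X, stats::model.matrix(~b)[, -1, drop = FALSE])
  }
  X
}

#' Single-SNP GWAS by least squares with MDS stratification correction
#'
#' Regresses the phenotype on each SNP plus batch effects and the leading
#' multidimensional-scaling coordinates of the identity-by-state matrix.
#' The additive variant fits the allele count and t-tests its coefficient;
#' the genotypic variant fits the 3-level genotype factor and tests
#' additive and dominance contrasts.
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param y phenotype vector.
#' @param mds MDS coordinates from \code{\link{mdsComponents}} (list or
#'   matrix); \code{NULL} with \code{nMds = 0} for no correction.
#' @param nMds number of leading MDS dimensions to include.
#' @param batch optional batch labels.
#' @param genotypic fit the genotype factor (tests dominance too) instead of
#'   the allele count.
#' @param minClass minimum class count for the genotypic fit.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return A \linkS4class{ScanResult}.
#' @export
lsMdsScan <- function(ge, y, mds = NULL, nMds = 35, batch = NULL,
                      genotypic = FALSE, minClass = 5, alpha = 0.05) {
  stopifnot(length(y) == nInds(ge))
  Xb <- .batchDesign(length(y), batch)
  if (nMds > 0) {
    M <- if (is.list(mds)) mds$coords else mds
    if (is.null(M)) stop("mds coordinates required when nMds > 0")
    if (ncol(M) < nMds) stop("mds has fewer than nMds columns")
    M <- M[, seq_len(nMds), drop = FALSE]
    colnames(M) <- paste0("MDS", seq_len(ncol(M)))
    Xb <- cbind(Xb, M)
    qrX <- qr(Xb)
    if (qrX$rank < ncol(Xb)) {
      warning("dropping ", ncol(Xb) - qrX$rank, " collinear covariate(s)")
      Xb <- Xb[, sort(qrX$pivot[seq_len(qrX$rank)]), drop = FALSE]
    }
  }
  .scanEngine(y, Xb, genoCodes(ge), snpInfo(ge), V = NULL,
              genotypic = genotypic, minClass = minClass,
              method = if (genotypic) "ls_mds_genotypic" else
                "ls_mds_additive", alpha = alpha)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the squared statistics divided by the median of
#' the 1-df chi-square distribution (0.4549364).
#'
#' @param statistics per-SNP t (or z) statistics, or chi-square values with
#'   \code{squared = TRUE}.
#' @param squared statistics are already chi-square distributed.
#' @return scalar lambda.
#' @export
inflationFactor <- function(statistics, squared = FALSE) {
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) < 100)
    warning("fewer than 100 test statistics; lambda is unstable")
  chi <- if (squared) statistics else statistics^2
  median(chi) / qchisq(0.5, df = 1)
}

#' Bonferroni threshold for m tests
#'
#' @param m number of tests.
#' @param alpha family-wise error level.
#' @return list(threshold = alpha/m, log10 = -log10(alpha/m)).
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  thr <- alpha / m
  list(threshold = thr, log10 = -log10(thr))
}

#' Combine significant SNPs across scan methods
#'
#' @param results list of \linkS4class{ScanResult} objects sharing a SNP
#'   panel.
#' @param threshold p-value threshold (default: Bonferroni at alpha = 0.05
#'   over the shared panel size).
#' @param useDominance also declare significance from the dominance test.
#' @return list with per-SNP flag data.frame (\code{flags}), the union of
#'   significant SNP ids (\code{union}), per-method sets (\code{sets}) and
#'   the pairwise overlap-count matrix (\code{overlap}).
#' @export
significantSnps <- function(results, threshold = NULL, useDominance = TRUE) {
  if (is(results, "ScanResult")) results <- list(results)
  ids <- results[[1]]@table$snp
  for (r in results) stopifnot(identical(r@table$snp, ids))
  if (is.null(threshold))
    threshold <- bonferroniThreshold(length(ids))$threshold
  sets <- lapply(results, function(r) {
    p <- r@table$pAdd
    if (useDominance) p <- pmin(p, r@table$pDom, na.rm = TRUE)
    ids[!is.na(p) & p < threshold]
  })
  names(sets) <- vapply(results, function(r) r@method, "")
  flags <- data.frame(snp = ids, stringsAsFactors = FALSE)
  for (nm in names(sets)) flags[[nm]] <- ids %in% sets[[nm]]
  un <- sort(unique(unlist(sets)))
  k <- length(sets)
  ov <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(flags = flags, union = un, sets = sets, overlap = ov,
       threshold = threshold)
}

#' Write a scan result as TSV
#' @param scan a \linkS4class{ScanResult}.
#' @param path output file.
#' @export
writeScan <- function(scan, path) {
  tb <- scan@table
  tb$method <- scan@method
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
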