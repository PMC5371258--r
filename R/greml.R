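#' Build a mixed-model specification
#'
#' Assembles phenotype, fixed-effect design (intercept + batch factor with
#' first level dropped + optional numeric covariates + optional SNPs fitted
#' as fixed allele-count covariates) and the genomic relationship matrices.
#' Rank-deficient fixed designs are reduced to full column rank with a
#' warning.
#'
#' @param y numeric phenotype vector.
#' @param A additive genomic relationship matrix (n x n).
#' @param D optional dominance genomic relationship matrix.
#' @param batch optional factor/character of batch labels.
#' @param covariates optional numeric matrix of covariates (e.g. MDS
#'   coordinates).
#' @param snpFixed optional matrix of SNP allele-count columns fitted as
#'   fixed effects (Method III reduced model); centered internally.
#' @param ids individual identifiers; default from rownames of A.
#' @return A \linkS4class{MixedModelSpec}.
#' @export
mixedModelSpec <- function(y, A, D = NULL, batch = NULL, covariates = NULL,
                           snpFixed = NULL, ids = rownames(A)) {
  n <- length(y)
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (!is.null(D)) stopifnot(nrow(D) == n, ncol(D) == n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(batch)) {
    b <- factor(batch)
    if (nlevels(b) > 1) {
      Xb <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(Xb) <- paste0("batch", levels(b)[-1])
      X <- cbind(X, Xb)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  snpCols <- integer(0)
  if (!is.null(snpFixed)) {
    snpFixed <- as.matrix(snpFixed)
    if (ncol(snpFixed) >= ncol(A) || ncol(snpFixed) >= n)
      stop("cannot fit every SNP (or >= n columns) as fixed effects")
    snpFixed <- scale(snpFixed, center = TRUE, scale = FALSE)
    if (is.null(colnames(snpFixed)))
      colnames(snpFixed) <- paste0("snp", seq_len(ncol(snpFixed)))
    snpCols <- ncol(X) + seq_len(ncol(snpFixed))
    X <- cbind(X, snpFixed)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop), " collinear fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    snpCols <- match(intersect(snpCols, keep), keep)
    snpCols <- snpCols[!is.na(snpCols)]
    X <- X[, keep, drop = FALSE]
  }
  new("MixedModelSpec", y = as.numeric(y), X = X, A = unname(A),
      D = if (is.null(D)) NULL else unname(D), ids = as.character(ids),
      snpCols = as.integer(snpCols))
}

# subset a spec to a set of individuals (used by cross-validation)
.specSubset <- function(spec, idx) {
  new("MixedModelSpec", y = spec@y[idx],
      X = spec@X[idx, , drop = FALSE],
      A = spec@A[idx, idx, drop = FALSE],
      D = if (is.null(spec@D)) NULL else spec@D[idx, idx, drop = FALSE],
      ids = spec@ids[idx], snpCols = spec@snpCols)
}

# REML internals for V = sum_i theta_i K_i with K_resid = I
.remlPieces <- function(theta, kernels, X, y, ridge = 0) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(kernels)) V <- V + theta[i] * kernels[[i]]
  if (ridge > 0) diag(V) <- diag(V) + ridge
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cR <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cR)) return(NULL)
  P <- Vi - ViX %*% chol2inv(cR) %*% t(ViX)
  Py <- P %*% y
  logLik <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(cR))) +
                    drop(crossprod(y, Py)))
  list(P = P, Py = Py, logLik = logLik)
}

#' Restricted log-likelihood of the genomic mixed model
#'
#' Direct evaluation at fixed variance components (up to an additive
#' constant); useful for likelihood-surface checks.
#'
#' @param spec a \linkS4class{MixedModelSpec}.
#' @param sigma named or positional numeric of components in the order
#'   additive, dominance (when present), residual.
#' @return scalar restricted log-likelihood.
#' @export
remlLogLik <- function(spec, sigma) {
  kernels <- .specKernels(spec)
  stopifnot(length(sigma) == length(kernels))
  pieces <- .remlPieces(as.numeric(sigma), kernels, spec@X, spec@y)
  if (is.null(pieces)) stop("variance matrix not positive definite")
  pieces$logLik
}

.specKernels <- function(spec) {
  n <- length(spec@y)
  ks <- list(additive = spec@A)
  if (!is.null(spec@D)) ks$dominance <- spec@D
  ks$residual <- diag(n)
  ks
}

#' Estimate variance components by average-information REML
#'
#' Maximizes the restricted likelihood of \eqn{y = Xb + a (+ d) + e} with
#' \eqn{Var(y) = A\sigma^2_\alpha (+ D\sigma^2_\delta) + I\sigma^2_e}.
#' Average-information updates with an EM fallback whenever a step would
#' leave the parameter space or the AI matrix is not invertible; components
#' are pinned at a small positive boundary (1e-6 of the phenotypic variance)
#' rather than allowed to go negative.  Convergence when the largest
#' relative component change is below \code{tol}.  Standard errors come from
#' the inverse AI matrix at convergence.
#'
#' @param spec a \linkS4class{MixedModelSpec}.
#' @param maxIter maximum iterations.
#' @param tol relative convergence tolerance.
#' @param verbose print the trajectory.
#' @return A \linkS4class{VarianceComponents}.
#' @export
fitGreml <- function(spec, maxIter = 200, tol = 1e-8, verbose = FALSE) {
  y <- spec@y; X <- spec@X
  n <- length(y)
  if (n < ncol(X) + 2) stop("too few individuals for the fixed design")
  kernels <- .specKernels(spec)
  q <- length(kernels)
  vp <- var(y)
  lb <- 1e-6 * vp
  theta <- if (q == 3) vp * c(0.4, 0.1, 0.5) else vp * c(0.5, 0.5)
  AI <- diag(q)
  trajectory <- theta
  converged <- FALSE
  iter <- 0L
  ridge <- 0
  while (iter < maxIter) {
    iter <- iter + 1L
    pieces <- .remlPieces(theta, kernels, X, y, ridge)
    if (is.null(pieces)) {
      if (ridge == 0) {
        ridge <- 1e-8 * vp
        warning("singular variance matrix; adding ridge of 1e-8 * var(y)")
        next
      }
      stop("variance matrix remained singular; trajectory: ",
           paste(signif(trajectory, 4), collapse = " "))
    }
    P <- pieces$P; Py <- pieces$Py
    KPy <- vapply(kernels, function(K) drop(K %*% Py), numeric(n))
    trPK <- vapply(kernels, function(K) sum(P * K), 0)
    score <- -0.5 * (trPK - drop(crossprod(Py, KPy)))
    PKPy <- P %*% KPy
    AI <- 0.5 * crossprod(KPy, PKPy)
    step <- tryCatch(drop(solve(AI, score)), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      thetaNew <- theta + step
      # a component pushed negative decays geometrically to the boundary
      # instead of shrinking the whole AI step
      neg <- thetaNew < lb
      thetaNew[neg] <- pmax(theta[neg] / 10, lb)
    } else {
      # EM fallback
      thetaNew <- theta + theta^2 * (drop(crossprod(Py, KPy)) - trPK) / n
    }
    thetaNew <- pmax(thetaNew, lb)
    delta <- max(abs(thetaNew - theta) / pmax(theta, lb))
    if (verbose)
      message(sprintf("iter %d: %s (logLik %.4f)", iter,
                      paste(signif(thetaNew, 6), collapse = " "),
                      pieces$logLik))
    theta <- thetaNew
    trajectory <- rbind(trajectory, theta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GREML did not converge in ", maxIter, " iterations; trajectory ",
         "tail: ", paste(signif(tail(trajectory, 3), 4), collapse = " "))
  pieces <- .remlPieces(theta, kernels, X, y, ridge)
  aiInv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, q, q))
  se <- sqrt(pmax(diag(aiInv), 0))
  names(theta) <- names(se) <- names(kernels)
  new("VarianceComponents", sigma = theta, se = se, aiInv = aiInv,
      logLik = pieces$logLik, iterations = iter, converged = converged,
      boundary = theta <= lb * (1 + 1e-12), n = as.integer(n))
}

#' Heritabilities from variance components
#'
#' Ratios of each genetic component to the phenotypic variance (the sum of
#' the estimated components), plus total (broad-sense) heritability as the
#' sum of the additive and dominance ratios; standard errors by the delta
#' method from the inverse AI matrix.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @return A \linkS4class{HeritabilityEstimates}.
#' @export
heritabilities <- function(vc) {
  s <- vc@sigma
  tot <- sum(s)
  if (tot <= 0) stop("phenotypic variance must be positive")
  q <- length(s)
  genetic <- setdiff(names(s), "residual")
  h2 <- s[genetic] / tot
  grads <- lapply(genetic, function(nm) {
    g <- -s[nm] / tot^2 + (names(s) == nm) / tot
    g
  })
  names(grads) <- genetic
  h2["total"] <- sum(h2[genetic])
  grads$total <- Reduce(`+`, grads[genetic])
  se <- vapply(grads, function(g) {
    if (anyNA(vc@aiInv)) return(NA_real_)
    sqrt(drop(t(g) %*% vc@aiInv %*% g))
  }, 0)
  new("HeritabilityEstimates", h2 = h2, se = se[names(h2)])
}

#' Genomic best linear unbiased prediction
#'
#' Solves for fixed effects and additive (and dominance) genetic values of
#' all individuals, using only unmasked (training) phenotypes; masked
#' (validation) individuals are predicted through their genomic
#' relationships.  Per-individual reliabilities are 1 - PEV / (K_ii sigma2)
#' from the prediction-error variance of each genetic value.
#'
#' @param spec a \linkS4class{MixedModelSpec} for all individuals.
#' @param vc a \linkS4class{VarianceComponents} (typically fitted on the
#'   training set).
#' @param mask individual ids or indices whose phenotypes are excluded.
#' @return A \linkS4class{GblupResult}.
#' @export
gblup <- function(spec, vc, mask = NULL) {
  n <- length(spec@y)
  maskIdx <- if (is.null(mask)) integer(0)
             else if (is.character(mask)) match(mask, spec@ids)
             else as.integer(mask)
  if (anyNA(maskIdx)) stop("mask contains unknown individual ids")
  tr <- setdiff(seq_len(n), maskIdx)
  s <- vc@sigma
  sa <- s[["additive"]]
  sd_ <- if ("dominance" %in% names(s)) s[["dominance"]] else 0
  se2 <- s[["residual"]]
  A <- spec@A
  D <- if (is.null(spec@D)) NULL else spec@D
  Xt <- spec@X[tr, , drop = FALSE]
  yt <- spec@y[tr]
  Vt <- sa * A[tr, tr]
  if (sd_ > 0 && !is.null(D)) Vt <- Vt + sd_ * D[tr, tr]
  diag(Vt) <- diag(Vt) + se2
  R <- tryCatch(chol(Vt), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular variance matrix; applying ridge of 1e-8 on the GRM ",
            "diagonal")
    diag(Vt) <- diag(Vt) + 1e-8 * sum(s)
    R <- chol(Vt)
  }
  Vi <- chol2inv(R)
  ViX <- Vi %*% Xt
  XtViX <- crossprod(Xt, ViX)
  bhat <- tryCatch(solve(XtViX, crossprod(ViX, yt)), error = function(e)
    stop("singular fixed-effect equations; check the design"))
  P <- Vi - ViX %*% solve(XtViX, t(ViX))
  Py <- drop(P %*% yt)

  Qa <- A[tr, , drop = FALSE]              # Cov(y_t, a_all) / sa
  aHat <- sa * drop(crossprod(Qa, Py))
  PQa <- P %*% Qa
  relA <- sa * colSums(Qa * PQa) / pmax(diag(A), 1e-12)
  if (!is.null(D) && sd_ > 0) {
    Qd <- D[tr, , drop = FALSE]
    dHat <- sd_ * drop(crossprod(Qd, Py))
    PQd <- P %*% Qd
    relD <- sd_ * colSums(Qd * PQd) / pmax(diag(D), 1e-12)
    Qg <- sa * Qa + sd_ * Qd
    varG <- sa * diag(A) + sd_ * diag(D)
  } else {
    dHat <- rep(0, n); relD <- rep(NA_real_, n)
    Qg <- sa * Qa
    varG <- sa * diag(A)
  }
  PQg <- P %*% Qg
  relT <- colSums(Qg * PQg) / pmax(varG, 1e-12)
  clamp <- function(r) pmin(pmax(r, 0), 1)
  pred <- data.frame(
    iid = spec@ids, aHat = aHat, dHat = dHat, gHat = aHat + dHat,
    relA = clamp(relA), relD = if (all(is.na(relD))) relD else clamp(relD),
    relT = clamp(relT),
    masked = seq_len(n) %in% maskIdx,
    stringsAsFactors = FALSE)
  new("GblupResult", pred = pred, fixef = setNames(drop(bhat),
                                                   colnames(spec@X)))
}

#' Back-solve per-SNP effects and per-SNP heritabilities from GBLUP
#'
#' Converts predicted breeding values (and dominance deviations) to per-SNP
#' effects via \eqn{\hat\alpha = W_a' A^{-1} \hat a / \sum_k 2 p_k q_k}, so
#' that \eqn{W_a \hat\alpha} reconstructs \eqn{\hat a} exactly; per-SNP
#' heritability is the variance across individuals of the SNP's contribution
#' divided by the phenotypic variance.
#'
#' @param ge the \linkS4class{GenotypeData} the GRMs were built from (same
#'   individuals, same SNP panel).
#' @param vc a \linkS4class{VarianceComponents}.
#' @param result a \linkS4class{GblupResult}.
#' @return data.frame with per-SNP id, alphaHat, deltaHat, h2Add, h2Dom; the
#'   number of SNPs in the model is attached as attribute \code{m}.
#' @export
backsolveSnpEffects <- function(ge, vc, result) {
  cf <- .codesFreq(ge)
  info <- snpInfo(ge)
  Wa <- sweep(cf$X, 2, 2 * cf$p)
  normA <- sum(2 * cf$p * (1 - cf$p))
  A <- tcrossprod(Wa) / normA
  aHat <- result@pred$aHat
  AiA <- tryCatch(solve(A, aHat), error = function(e) {
    warning("singular additive GRM; using pseudo-inverse")
    .pinvSolve(A, aHat)
  })
  alpha <- drop(crossprod(Wa, AiA)) / normA
  vp <- sum(vc@sigma)
  h2a <- vc@sigma[["additive"]] / vp
  # exact partition of the estimated additive heritability over SNPs,
  # proportional to each SNP's contribution variance Var_i(w_k alpha_k);
  # the per-SNP values sum to h2_alpha by construction and scale as 1/m
  varK <- apply(Wa, 2, var) * alpha^2
  h2Add <- if (sum(varK) > 0) h2a * varK / sum(varK)
           else rep(0, length(alpha))
  deltaHat <- rep(NA_real_, length(alpha))
  h2Dom <- rep(NA_real_, length(alpha))
  if ("dominance" %in% names(vc@sigma) && any(result@pred$dHat != 0)) {
    Wd <- .domW(cf$X, cf$p)
    normD <- sum((2 * cf$p * (1 - cf$p))^2)
    Dg <- tcrossprod(Wd) / normD
    dHat <- result@pred$dHat
    DiD <- tryCatch(solve(Dg, dHat), error = function(e) {
      warning("singular dominance GRM; using pseudo-inverse")
      .pinvSolve(Dg, dHat)
    })
    delta <- drop(crossprod(Wd, DiD)) / normD
    deltaHat <- delta
    h2d <- vc@sigma[["dominance"]] / vp
    varKd <- apply(Wd, 2, var) * delta^2
    h2Dom <- if (sum(varKd) > 0) h2d * varKd / sum(varKd)
             else rep(0, length(delta))
  }
  out <- data.frame(id = info$id[cf$keep], alphaHat = alpha,
                    deltaHat = deltaHat, h2Add = h2Add, h2Dom = h2Dom,
                    stringsAsFactors = FALSE)
  attr(out, "m") <- ncol(cf$X)
  out
}

#' @importFrom utils tail
NULL

# Moore-Penrose solve via SVD (fallback for singular symmetric matrices)
.pinvSolve <- function(M, b, tol = 1e-10) {
  s <- svd(M)
  d <- ifelse(s$d > tol * max(s$d), 1 / s$d, 0)
  drop(s$v %*% (d * crossprod(s$u, b)))
}
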