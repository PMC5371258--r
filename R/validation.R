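#' Random fold plan for k-fold validation
#'
#' Default sizes are floor(n/k) per fold with the remainder added to the last
#' fold, so n = 2936 with k = 10 gives nine folds of 293 and one of 299.
#'
#' @param n number of individuals.
#' @param k number of folds.
#' @param sizes optional explicit fold sizes summing to n.
#' @param seed RNG seed for the random partition.
#' @return list(folds = list of index vectors, sizes, n, k, seed), class
#'   \code{FoldPlan}.
#' @export
makeFolds <- function(n, k = 10, sizes = NULL, seed = NULL) {
  if (k > n) stop("more folds than individuals")
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    sizes[k] <- sizes[k] + n %% k
  }
  if (sum(sizes) != n) stop("fold sizes must sum to n")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  folds <- split(perm, rep(seq_len(k), sizes))
  names(folds) <- paste0("fold", seq_len(k))
  structure(list(folds = folds, sizes = sizes, n = n, k = k, seed = seed),
            class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat("FoldPlan:", x$n, "individuals in", x$k, "folds (sizes",
      paste(x$sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Expected accuracy of predicting phenotypic values
#'
#' The product of the expected genetic accuracy (square root of reliability)
#' and the square root of heritability.
#'
#' @param R0j expected genetic accuracy in [0, 1].
#' @param h2j heritability in [0, 1].
#' @param digits optional rounding of the result.
#' @return scalar expected phenotypic accuracy.
#' @export
expectedPhenotypicAccuracy <- function(R0j, h2j, digits = NULL) {
  stopifnot(R0j >= 0, R0j <= 1, h2j >= 0, h2j <= 1)
  out <- R0j * sqrt(h2j)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Observed accuracy of predicting phenotypic values
#'
#' Pearson correlation between predicted genetic values and phenotypes of
#' validation individuals.  Phenotypes are used raw by default; set
#' \code{adjust} to a fixed-effect design to pre-adjust them.
#'
#' @param ghat predicted genetic values.
#' @param y phenotypes, same individuals.
#' @param adjust optional design matrix; y is replaced by its OLS residual.
#' @return scalar correlation.
#' @export
observedPhenotypicAccuracy <- function(ghat, y, adjust = NULL) {
  stopifnot(length(ghat) == length(y))
  if (length(y) < 3) stop("need at least 3 pairs")
  if (!is.null(adjust)) y <- lm.fit(as.matrix(adjust), y)$residuals
  if (sd(ghat) == 0 || sd(y) == 0)
    stop("zero variance; correlation undefined")
  cor(ghat, y)
}

#' k-fold cross-validation of genomic prediction
#'
#' For each fold: variance components are re-estimated by GREML on the
#' training individuals, GBLUP predicts the masked fold, and three accuracy
#' measures are collected per genetic component j (additive, dominance when
#' fitted, total): observed phenotypic accuracy (correlation of predicted
#' genetic value with the fold's phenotypes), expected genetic accuracy
#' (mean square-root reliability over the fold), and expected phenotypic
#' accuracy (genetic accuracy times the square root of the training-fold
#' heritability).
#'
#' @param spec a \linkS4class{MixedModelSpec} over all individuals.
#' @param plan a \code{\link{makeFolds}} plan over the same individuals.
#' @param refit re-estimate variance components per training fold (default);
#'   if \code{FALSE}, \code{vc} must be supplied.
#' @param vc optional \linkS4class{VarianceComponents} used for every fold
#'   when \code{refit = FALSE}.
#' @param adjust optionally pre-adjust validation phenotypes for the fixed
#'   effects before correlating.
#' @return An \linkS4class{AccuracyReport}.
#' @export
crossValidate <- function(spec, plan, refit = TRUE, vc = NULL,
                          adjust = FALSE) {
  stopifnot(inherits(plan, "FoldPlan"), plan$n == length(spec@y))
  rows <- list()
  for (f in seq_along(plan$folds)) {
    idx <- plan$folds[[f]]
    if (length(idx) < 2) {
      warning("fold ", f, " has fewer than 2 individuals; skipped")
      next
    }
    tr <- setdiff(seq_len(plan$n), idx)
    vcf <- if (refit) fitGreml(.specSubset(spec, tr)) else vc
    if (is.null(vcf)) stop("vc must be supplied when refit = FALSE")
    h2 <- heritabilities(vcf)@h2
    gb <- gblup(spec, vcf, mask = idx)
    pr <- gb@pred[idx, ]
    y0 <- spec@y[idx]
    if (isTRUE(adjust))
      y0 <- lm.fit(spec@X[idx, , drop = FALSE], y0)$residuals
    comps <- list(additive = list(g = pr$aHat, rel = pr$relA,
                                  h2 = h2[["additive"]]))
    if ("dominance" %in% names(h2)) {
      comps$dominance <- list(g = pr$dHat, rel = pr$relD,
                              h2 = h2[["dominance"]])
      comps$total <- list(g = pr$gHat, rel = pr$relT, h2 = h2[["total"]])
    } else {
      comps$total <- list(g = pr$gHat, rel = pr$relT, h2 = h2[["total"]])
    }
    for (nm in names(comps)) {
      cc <- comps[[nm]]
      obs <- if (sd(cc$g) == 0 || sd(y0) == 0) NA_real_ else cor(cc$g, y0)
      R0j <- mean(sqrt(pmax(cc$rel, 0)), na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        fold = f, component = nm, observed = obs, expectedGenetic = R0j,
        expectedPhenotypic = expectedPhenotypicAccuracy(min(R0j, 1), cc$h2),
        h2 = cc$h2, stringsAsFactors = FALSE)
    }
  }
  perFold <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  pooled <- do.call(rbind, lapply(split(perFold, perFold$component),
    function(d) data.frame(
      component = d$component[1],
      observed = mean(d$observed, na.rm = TRUE),
      observedSd = sd(d$observed, na.rm = TRUE),
      expectedGenetic = mean(d$expectedGenetic, na.rm = TRUE),
      expectedGeneticSd = sd(d$expectedGenetic, na.rm = TRUE),
      expectedPhenotypic = mean(d$expectedPhenotypic, na.rm = TRUE),
      expectedPhenotypicSd = sd(d$expectedPhenotypic, na.rm = TRUE),
      h2 = mean(d$h2), stringsAsFactors = FALSE)))
  rownames(pooled) <- NULL
  new("AccuracyReport", perFold = perFold, pooled = pooled)
}

#' @describeIn crossValidate pooled accuracy table
#' @param report an \linkS4class{AccuracyReport}
#' @export
pooledAccuracy <- function(report) report@pooled
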