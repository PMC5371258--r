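#' Resolve a SNP set against the panel
#'
#' Accepts a character vector of SNP ids or a region string
#' \code{"chr:start-end"} (1-based, inclusive) resolved against SNP
#' positions.
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param set SNP ids or a region string.
#' @return integer vector of SNP column indices.
#' @export
resolveSnpSet <- function(ge, set) {
  info <- snpInfo(ge)
  if (length(set) == 1 && grepl("^[^:]+:[0-9.eE+]+-[0-9.eE+]+$", set)) {
    chr <- sub(":.*$", "", set)
    rng <- as.numeric(strsplit(sub("^[^:]+:", "", set), "-")[[1]])
    idx <- which(as.character(info$chr) == chr & info$pos >= rng[1] &
                 info$pos <= rng[2])
    if (!length(idx)) stop("region ", set, " matches no SNPs")
    return(idx)
  }
  if (anyDuplicated(set)) stop("duplicate SNP ids in set")
  idx <- match(set, info$id)
  if (anyNA(idx))
    stop("unknown SNP id(s): ", paste(set[is.na(idx)], collapse = ", "))
  idx
}

#' Relative contribution statistic
#'
#' \eqn{c = 1 - reduced/full}: the fractional decrease of a heritability or
#' accuracy when moving from the full to the reduced model (positive when
#' the reduced model is smaller; multiply by 100 and negate for the
#' "decrease" sign convention of printed tables).
#'
#' @param full full-model value (non-zero).
#' @param reduced reduced-model value.
#' @return scalar c.
#' @export
contributionStats <- function(full, reduced) {
  if (any(full == 0)) stop("full-model value must be non-zero")
  1 - reduced / full
}

#' Method I: summed per-SNP heritability of a SNP set
#'
#' Sums the back-solved per-SNP heritabilities over the set.  The result
#' depends on the panel size m (per-SNP heritability scales roughly as 1/m),
#' which is why the removal and fixed-effect methods exist.
#'
#' @param perSnp per-SNP effect table from
#'   \code{\link{backsolveSnpEffects}}.
#' @param set SNP ids (subset of \code{perSnp$id}); \code{NULL} sums the
#'   whole panel.
#' @return named numeric: summed additive (and dominance, when available)
#'   heritability, with attribute \code{m} (panel size the estimates came
#'   from).
#' @export
sumSnpHeritability <- function(perSnp, set = NULL) {
  if (is.null(set)) idx <- seq_len(nrow(perSnp))
  else {
    idx <- match(set, perSnp$id)
    if (anyNA(idx))
      stop("unknown SNP id(s): ", paste(set[is.na(idx)], collapse = ", "))
  }
  out <- c(additive = sum(perSnp$h2Add[idx]),
           dominance = if (all(is.na(perSnp$h2Dom[idx]))) NA_real_
                       else sum(perSnp$h2Dom[idx], na.rm = TRUE))
  attr(out, "m") <- attr(perSnp, "m")
  out
}

# fit full + reduced model pair, optionally with CV accuracies, and package
# the report
.contributionReport <- function(method, setName, setSize, specFull,
                                specReduced, folds, seed, adjust = FALSE) {
  vcF <- fitGreml(specFull)
  vcR <- fitGreml(specReduced)
  h2F <- heritabilities(vcF)@h2
  h2R <- heritabilities(vcR)@h2
  full <- setNames(h2F, paste0("h2_", names(h2F)))
  reduced <- setNames(h2R[names(h2F)], paste0("h2_", names(h2F)))
  if (folds > 0) {
    plan <- makeFolds(length(specFull@y), k = folds, seed = seed)
    cvF <- pooledAccuracy(crossValidate(specFull, plan, adjust = adjust))
    cvR <- pooledAccuracy(crossValidate(specReduced, plan, adjust = adjust))
    comp <- if ("h2_dominance" %in% names(full)) "total" else "additive"
    fF <- cvF[cvF$component == comp, ]
    fR <- cvR[cvR$component == comp, ]
    full <- c(full, obsAccuracy = fF$observed,
              expPhenoAccuracy = fF$expectedPhenotypic,
              expGeneticAccuracy = fF$expectedGenetic)
    reduced <- c(reduced, obsAccuracy = fR$observed,
                 expPhenoAccuracy = fR$expectedPhenotypic,
                 expGeneticAccuracy = fR$expectedGenetic)
  }
  contrib <- 1 - reduced / full
  new("ContributionReport", method = method, setName = setName,
      setSize = as.integer(setSize), full = full, reduced = reduced,
      contribution = contrib)
}

#' Method II: SNP-set contribution by panel removal
#'
#' Rebuilds the genomic relationship matrices without the target SNPs,
#' refits GREML (and optionally reruns cross-validation), and reports
#' \eqn{c = 1 - reduced/full} for each heritability component and accuracy
#' flavor.  Because other SNPs in LD can absorb the removed signal, this is
#' a lower bound on the set's contribution.
#'
#' @param ge a post-QC \linkS4class{GenotypeData}.
#' @param y phenotype vector.
#' @param set SNP ids or region string (see \code{\link{resolveSnpSet}}).
#' @param batch optional batch labels.
#' @param includeDominance fit the dominance component.
#' @param folds number of CV folds for the accuracy contribution; 0 skips
#'   accuracy.
#' @param seed seed for the fold plan.
#' @param setName label for the report.
#' @return A \linkS4class{ContributionReport}.
#' @export
removalContribution <- function(ge, y, set, batch = NULL,
                                includeDominance = TRUE, folds = 0,
                                seed = 1, setName = "set") {
  idx <- resolveSnpSet(ge, set)
  if (nSnps(ge) - length(idx) < 10)
    stop("removal would leave fewer than 10 SNPs")
  geR <- ge[-idx, ]
  A <- additiveGRM(ge); D <- if (includeDominance) dominanceGRM(ge) else NULL
  AR <- additiveGRM(geR)
  DR <- if (includeDominance) dominanceGRM(geR) else NULL
  specF <- mixedModelSpec(y, A = A, D = D, batch = batch, ids = indIds(ge))
  specR <- mixedModelSpec(y, A = AR, D = DR, batch = batch, ids = indIds(ge))
  .contributionReport("II_removal", setName, length(idx), specF, specR,
                      folds, seed)
}

#' Method III: partial heritability and accuracy by fixed-SNP adjustment
#'
#' Keeps all SNPs in the genomic relationship matrices and fits the target
#' SNPs as fixed allele-count covariates (genotypic 2-df coding optional),
#' removing their genotypic values from the phenotype; GREML and optionally
#' cross-validation are rerun under this reduced model.  Because LD partners
#' of the fixed SNPs are also absorbed, this is an upper bound on the set's
#' contribution.
#'
#' @inheritParams removalContribution
#' @param coding "additive" (allele count, 1 df per SNP) or "genotypic"
#'   (2-df genotype factor per SNP).
#' @return A \linkS4class{ContributionReport}.
#' @export
partialHeritability <- function(ge, y, set, batch = NULL,
                                includeDominance = TRUE, folds = 0,
                                seed = 1, coding = c("additive", "genotypic"),
                                setName = "set") {
  coding <- match.arg(coding)
  idx <- resolveSnpSet(ge, set)
  if (length(idx) >= nSnps(ge))
    stop("cannot fit every SNP in the panel as fixed effects")
  X <- imputedCodes(ge)
  S <- X[, idx, drop = FALSE]
  if (coding == "genotypic")
    S <- cbind(S, matrix(as.numeric(X[, idx, drop = FALSE] == 1),
                         nrow(X), length(idx)))
  A <- additiveGRM(ge); D <- if (includeDominance) dominanceGRM(ge) else NULL
  specF <- mixedModelSpec(y, A = A, D = D, batch = batch, ids = indIds(ge))
  specR <- suppressWarnings(
    mixedModelSpec(y, A = A, D = D, batch = batch, snpFixed = S,
                   ids = indIds(ge)))
  .contributionReport("III_fixed", setName, length(idx), specF, specR,
                      folds, seed)
}

#' Stability of partial heritability under panel subsampling
#'
#' Recomputes the Method III contribution while the SNP panel is subsampled
#' to each fraction (the target set is always retained); reports the
#' contribution per fraction and the maximum absolute spread.
#'
#' @inheritParams partialHeritability
#' @param fractions panel fractions in (0, 1].
#' @return list(table = data.frame(fraction, m, contribution per
#'   component...), spread = named numeric of max absolute spreads).
#' @export
partialHeritabilityStability <- function(ge, y, set, fractions = c(0.5, 1),
                                         batch = NULL,
                                         includeDominance = FALSE,
                                         seed = 1) {
  idx <- resolveSnpSet(ge, set)
  rows <- list()
  for (fr in fractions) {
    keep <- if (fr >= 1) seq_len(nSnps(ge)) else {
      set.seed(seed)
      sort(union(idx, sample(seq_len(nSnps(ge)),
                             max(10, round(fr * nSnps(ge))))))
    }
    sub <- ge[keep, ]
    setIds <- snpInfo(ge)$id[idx]
    rep <- partialHeritability(sub, y, setIds, batch = batch,
                               includeDominance = includeDominance,
                               folds = 0, setName = "stability")
    cv <- contributionValues(rep)
    rows[[length(rows) + 1]] <- data.frame(
      fraction = fr, m = length(keep), t(cv), check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  comp <- setdiff(colnames(tab), c("fraction", "m"))
  spread <- vapply(comp, function(cn) diff(range(tab[[cn]])), 0)
  list(table = tab, spread = spread)
}
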