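#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats var cor sd median rnorm runif rbinom pchisq qchisq
#'   pt cmdscale lm.fit setNames
#' @importFrom utils read.table write.table head
NULL

#' GenotypeData: SNP genotypes with marker and individual annotation
#'
#' Container for diploid biallelic SNP genotypes, stored as a
#' \linkS4class{SummarizedExperiment} with one assay \code{"geno"} holding
#' alternate-allele counts (0, 1, 2, or NA) with SNPs as rows and individuals
#' as columns.  \code{rowData} carries per-SNP metadata (\code{chr},
#' \code{pos}, \code{id}, \code{ref}, \code{alt}); \code{colData} carries
#' per-individual annotation (e.g. sire, litter, batch, phenotype when
#' available).
#'
#' User-facing accessors present genotypes in the individuals x SNPs
#' orientation used by the relationship-matrix and scan machinery.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- NULL
  g <- SummarizedExperiment::assay(object, "geno")
  bad <- !(g %in% c(0L, 1L, 2L) | is.na(g))
  if (any(bad))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chr", "pos", "id")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain chr, pos, id")
  else {
    if (anyDuplicated(rd$id))
      msg <- c(msg, "SNP ids must be unique")
    byChr <- split(rd$pos, as.character(rd$chr))
    if (any(vapply(byChr, function(p) is.unsorted(p, strictly = TRUE), TRUE)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "individual ids must be present and unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param codes integer matrix of alternate-allele counts, individuals x SNPs.
#' @param snpInfo data.frame with columns \code{chr}, \code{pos}, \code{id}
#'   and optionally \code{ref}, \code{alt}.  Missing ids are normalized to
#'   \code{S<chr>_<pos>}.
#' @param indIds character vector of individual identifiers; defaults to the
#'   row names of \code{codes}.
#' @param indData optional data.frame of per-individual annotation.
#' @return A \linkS4class{GenotypeData} object.
#' @export
GenotypeData <- function(codes, snpInfo, indIds = rownames(codes),
                         indData = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(indIds)) indIds <- paste0("IND", seq_len(nrow(codes)))
  snpInfo <- as.data.frame(snpInfo)
  if (is.null(snpInfo$id) || any(is.na(snpInfo$id)) ||
      any(!nzchar(snpInfo$id))) {
    auto <- paste0("S", snpInfo$chr, "_", snpInfo$pos)
    if (is.null(snpInfo$id)) snpInfo$id <- auto
    else {
      fix <- is.na(snpInfo$id) | !nzchar(snpInfo$id)
      snpInfo$id[fix] <- auto[fix]
    }
  }
  if (is.null(snpInfo$ref)) snpInfo$ref <- "A"
  if (is.null(snpInfo$alt)) snpInfo$alt <- "B"
  ord <- order(factor(snpInfo$chr, levels = unique(snpInfo$chr)), snpInfo$pos)
  snpInfo <- snpInfo[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  cd <- if (is.null(indData)) S4Vectors::DataFrame(row.names = indIds)
        else S4Vectors::DataFrame(indData, row.names = indIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = t(codes)),
    rowData = S4Vectors::DataFrame(snpInfo, row.names = snpInfo$id),
    colData = cd)
  new("GenotypeData", se)
}

#' @describeIn GenotypeData genotype codes, individuals x SNPs
#' @param x,object a GenotypeData object
#' @export
genoCodes <- function(x) t(SummarizedExperiment::assay(x, "geno"))

#' @describeIn GenotypeData per-SNP metadata as a data.frame
#' @export
snpInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn GenotypeData individual identifiers
#' @export
indIds <- function(x) colnames(x)

#' @describeIn GenotypeData number of SNPs
#' @export
nSnps <- function(x) nrow(x)

#' @describeIn GenotypeData number of individuals
#' @export
nInds <- function(x) ncol(x)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "individuals x", nrow(object), "SNPs\n")
  chr <- unique(as.character(SummarizedExperiment::rowData(object)$chr))
  cat("  chromosomes:", length(chr), "\n")
  nNA <- sum(is.na(SummarizedExperiment::assay(object, "geno")))
  if (nNA > 0) cat("  missing genotypes:", nNA, "\n")
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  individual annotation:", paste(cd, collapse = ", "), "\n")
})

#' VarianceComponents: GREML estimates of variance components
#'
#' @slot sigma named numeric: estimated variances (additive, optionally
#'   dominance, residual).
#' @slot se delta/AI standard errors of the components.
#' @slot aiInv inverse average-information matrix at convergence.
#' @slot logLik restricted log-likelihood (up to an additive constant).
#' @slot iterations number of iterations run.
#' @slot converged logical.
#' @slot boundary logical vector: component pinned at the lower boundary.
#' @slot n number of phenotyped individuals.
#' @exportClass VarianceComponents
setClass("VarianceComponents", representation(
  sigma = "numeric", se = "numeric", aiInv = "matrix", logLik = "numeric",
  iterations = "integer", converged = "logical", boundary = "logical",
  n = "integer"))

#' @describeIn VarianceComponents named vector of variance components
#' @param object,vc a VarianceComponents object
#' @export
varComp <- function(vc) vc@sigma

#' @describeIn VarianceComponents total (phenotypic) variance, the sum of the
#'   components
#' @export
phenoVar <- function(vc) sum(vc@sigma)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (GREML", if (object@converged) "converged"
      else "NOT converged", "in", object@iterations, "iterations)\n")
  out <- data.frame(estimate = object@sigma, se = object@se,
                    boundary = object@boundary)
  print(round(out, 5))
  cat("  sigma2_y =", round(sum(object@sigma), 5),
      " logLik =", round(object@logLik, 3), "\n")
})

#' HeritabilityEstimates: variance ratios with delta-method standard errors
#'
#' @slot h2 named numeric: additive, dominance (when fitted) and total
#'   (broad-sense) heritability, each a ratio of a variance component to the
#'   phenotypic variance.
#' @slot se delta-method standard errors.
#' @exportClass HeritabilityEstimates
setClass("HeritabilityEstimates",
         representation(h2 = "numeric", se = "numeric"))

setMethod("show", "HeritabilityEstimates", function(object) {
  cat("HeritabilityEstimates\n")
  print(round(data.frame(h2 = object@h2, se = object@se), 4))
})

#' @describeIn HeritabilityEstimates named vector of heritabilities
#' @param x a HeritabilityEstimates object
#' @export
h2values <- function(x) x@h2

#' MixedModelSpec: data and design for the genomic mixed model
#'
#' Bundles the phenotype vector, fixed-effect design (intercept + batch +
#' optional covariates + optional SNPs fitted as fixed effects), and the
#' additive and optional dominance genomic relationship matrices, all aligned
#' on the same individuals (one observation per individual).
#'
#' @slot y numeric phenotype vector.
#' @slot X fixed-effect design matrix, full column rank.
#' @slot A additive genomic relationship matrix.
#' @slot D dominance genomic relationship matrix or NULL.
#' @slot ids individual identifiers.
#' @slot snpCols columns of X that hold fixed SNP covariates.
#' @exportClass MixedModelSpec
setClass("MixedModelSpec", representation(
  y = "numeric", X = "matrix", A = "matrix", D = "ANY", ids = "character",
  snpCols = "integer"))

setMethod("show", "MixedModelSpec", function(object) {
  cat("MixedModelSpec: n =", length(object@y), ", fixed effects =",
      ncol(object@X), if (!is.null(object@D)) "(additive + dominance)"
      else "(additive only)", "\n")
  if (length(object@snpCols))
    cat("  SNPs fitted as fixed effects:", length(object@snpCols), "\n")
})

#' GblupResult: genomic predictions with reliabilities
#'
#' @slot pred data.frame with one row per individual: iid, aHat, dHat, gHat,
#'   relA, relD, relT, masked.
#' @slot fixef named numeric of fixed-effect solutions.
#' @exportClass GblupResult
setClass("GblupResult", representation(pred = "data.frame", fixef = "numeric"))

setMethod("show", "GblupResult", function(object) {
  cat("GblupResult:", nrow(object@pred), "individuals (",
      sum(object@pred$masked), "masked )\n")
  print(head(object@pred, 4))
})

#' @describeIn GblupResult per-individual predictions as a data.frame
#' @param x a GblupResult object
#' @export
predictions <- function(x) x@pred

#' ScanResult: single-SNP association scan
#'
#' @slot table data.frame with per-SNP estimates, t statistics and p-values.
#' @slot method scan method tag.
#' @slot lambda genomic inflation factor of the additive test statistics.
#' @slot threshold Bonferroni p-value threshold used for flagging.
#' @exportClass ScanResult
setClass("ScanResult", representation(
  table = "data.frame", method = "character", lambda = "numeric",
  threshold = "numeric"))

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult [", object@method, "]:", nrow(object@table), "SNPs, lambda =",
      round(object@lambda, 3), ", Bonferroni p <",
      signif(object@threshold, 3), "\n")
  print(head(object@table[order(object@table$pAdd), ], 4))
})

#' @describeIn ScanResult per-SNP scan table
#' @param x a ScanResult object
#' @export
scanTable <- function(x) x@table

#' AccuracyReport: cross-validated prediction accuracies
#'
#' Per-fold and pooled values of the three accuracy measures: observed
#' phenotypic accuracy (correlation of predicted genetic value with
#' phenotype), expected genetic accuracy (mean square-root reliability), and
#' expected phenotypic accuracy (genetic accuracy times the square root of
#' heritability), each for additive, dominance (when fitted) and total
#' genetic values.
#'
#' @slot perFold data.frame with one row per fold and component.
#' @slot pooled data.frame of means and SDs across folds.
#' @exportClass AccuracyReport
setClass("AccuracyReport",
         representation(perFold = "data.frame", pooled = "data.frame"))

setMethod("show", "AccuracyReport", function(object) {
  cat("AccuracyReport over", length(unique(object@perFold$fold)), "folds\n")
  print(round(object@pooled[, sapply(object@pooled, is.numeric)], 3))
})

#' ContributionReport: SNP-set contribution to heritability and accuracy
#'
#' @slot method one of "I_sum", "II_removal", "III_fixed".
#' @slot setName name of the SNP set.
#' @slot setSize number of SNPs in the set.
#' @slot full named numeric of full-model quantities.
#' @slot reduced named numeric of reduced-model quantities.
#' @slot contribution named numeric of c = 1 - reduced/full values.
#' @exportClass ContributionReport
setClass("ContributionReport", representation(
  method = "character", setName = "character", setSize = "integer",
  full = "numeric", reduced = "numeric", contribution = "numeric"))

setMethod("show", "ContributionReport", function(object) {
  cat("ContributionReport [method", object@method, "] set:", object@setName,
      "(", object@setSize, "SNPs )\n")
  out <- data.frame(full = object@full,
                    reduced = object@reduced[names(object@full)])
  out$contribution_pct <- 100 * object@contribution[names(object@full)]
  print(round(out, 4))
})

#' @describeIn ContributionReport named contribution values (c = 1 -
#'   reduced/full)
#' @param x a ContributionReport object
#' @export
contributionValues <- function(x) x@contribution
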