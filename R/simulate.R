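#' Simulation configuration
#'
#' Parameters of the gene-dropping simulator of a paternal half-sib population
#' typed at genome-wide SNPs.  Defaults emulate a commercial Duroc nucleus
#' population: 79 sires mated to 1456 unique dams (one litter each) with one
#' to three phenotyped offspring per litter, ~41k autosomal SNPs with minor
#' allele frequency above 0.05 and local linkage disequilibrium, a
#' near-bell-shaped integer trait with mean 10.72 and SD 1.72, narrow-sense
#' heritability 0.365, dominance heritability 0.035, and year-month batch
#' effects over two years (24 levels).
#'
#' @param nSires number of sires.
#' @param nLitters number of litters; each litter has a unique dam.
#' @param litterSize integer vector (min, max) of offspring per litter.
#' @param nSnps total number of SNPs across all chromosomes.
#' @param nChromosomes number of autosomes the SNPs are spread over.
#' @param mafRange (min, max) founder allele frequencies in (0, 0.5].
#' @param ldDecay correlation between adjacent markers on founder haplotypes,
#'   in [0, 1).  First-order Markov LD model.
#' @param nQtl number of causal SNPs drawn from the panel; default
#'   min(200, nSnps).
#' @param h2Add target narrow-sense heritability (realized on the sample).
#' @param h2Dom target dominance heritability (realized on the sample).
#' @param nBatches number of year-month batch levels.
#' @param batchSd SD of batch effects, in phenotypic-SD units.
#' @param phenoMean,phenoSd target phenotypic mean and SD.
#' @param discretize round phenotypes to integers (counted trait).
#' @param recombRate per-adjacent-interval recombination probability; default
#'   \code{NULL} sets one expected crossover per chromosome (~1 Morgan).
#' @param seed RNG seed; every simulation call is seeded from it.
#' @return An object of class \code{SimConfig} (validated list).
#' @export
simConfig <- function(nSires = 79, nLitters = 1456, litterSize = c(1, 3),
                      nSnps = 41108, nChromosomes = 18,
                      mafRange = c(0.05, 0.5), ldDecay = 0.7, nQtl = NULL,
                      h2Add = 0.365, h2Dom = 0.035, nBatches = 24,
                      batchSd = 0.25, phenoMean = 10.72, phenoSd = 1.72,
                      discretize = TRUE, recombRate = NULL, seed = 1L) {
  stopifnot(length(litterSize) == 2, length(mafRange) == 2)
  if (nSires < 1 || nLitters < 1 || nSnps < 1 || nChromosomes < 1)
    stop("counts must be positive")
  if (litterSize[1] < 1 || litterSize[1] > litterSize[2])
    stop("litter sizes must be >= 1 and min <= max")
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  if (ldDecay < 0 || ldDecay >= 1) stop("ldDecay must be in [0, 1)")
  if (h2Add < 0 || h2Dom < 0 || h2Add + h2Dom >= 1)
    stop("h2Add + h2Dom must be in [0, 1)")
  if (is.null(nQtl)) nQtl <- min(200L, nSnps)
  if (nQtl > nSnps) stop("nQtl must not exceed nSnps")
  structure(list(
    nSires = as.integer(nSires), nLitters = as.integer(nLitters),
    litterSize = as.integer(litterSize), nSnps = as.integer(nSnps),
    nChromosomes = as.integer(nChromosomes), mafRange = as.numeric(mafRange),
    ldDecay = ldDecay, nQtl = as.integer(nQtl), h2Add = h2Add, h2Dom = h2Dom,
    nBatches = as.integer(nBatches), batchSd = batchSd, phenoMean = phenoMean,
    phenoSd = phenoSd, discretize = discretize, recombRate = recombRate,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Simulate a paternal half-sib pedigree with litters and batches
#'
#' Assigns each litter a sire (every sire receives at least one litter when
#' possible), a unique dam, a year-month batch label, and a litter size drawn
#' uniformly from the configured range.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return data.frame with columns iid, sire, dam, litter, batch; one row per
#'   offspring.
#' @export
simulatePedigree <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nL <- config$nLitters
  # guarantee coverage of all sires, then random assignment
  sireOfLitter <- if (nL >= config$nSires)
    sample(c(seq_len(config$nSires),
             sample.int(config$nSires, nL - config$nSires, replace = TRUE)))
  else sample.int(config$nSires, nL)
  sizes <- sample(seq(config$litterSize[1], config$litterSize[2]), nL,
                  replace = TRUE)
  batchOfLitter <- sample.int(config$nBatches, nL, replace = TRUE)
  litter <- rep(seq_len(nL), sizes)
  n <- length(litter)
  data.frame(
    iid = sprintf("IND%05d", seq_len(n)),
    sire = sprintf("SIRE%03d", sireOfLitter[litter]),
    dam = sprintf("DAM%04d", litter),
    litter = sprintf("LIT%04d", litter),
    batch = sprintf("B%02d", batchOfLitter[litter]),
    stringsAsFactors = FALSE)
}

# founder haplotypes: first-order Markov chain over markers with target
# adjacent correlation r; chain restarts at chromosome boundaries
.simHaplotypes <- function(nHap, p, chrIndex, r) {
  m <- length(p)
  H <- matrix(0L, nHap, m)
  q <- 1 - p
  H[, 1] <- rbinom(nHap, 1L, p[1])
  if (m > 1) for (k in 2:m) {
    if (chrIndex[k] != chrIndex[k - 1] || r == 0) {
      H[, k] <- rbinom(nHap, 1L, p[k])
    } else {
      s <- sqrt(p[k] * q[k])
      p1 <- pmin(pmax(p[k] + r * s * sqrt(q[k - 1] / p[k - 1]), 0), 1)
      p0 <- pmin(pmax(p[k] - r * s * sqrt(p[k - 1] / q[k - 1]), 0), 1)
      pr <- ifelse(H[, k - 1] == 1L, p1, p0)
      H[, k] <- rbinom(nHap, 1L, pr)
    }
  }
  H
}

# one gamete per row of the two parental haplotypes, with recombination
# probability cvec[k] between markers k-1 and k (0.5 across chromosomes)
.gamete <- function(h1, h2, cvec) {
  m <- length(h1)
  sel <- cumsum(c(rbinom(1, 1L, 0.5), rbinom(m - 1, 1L, cvec))) %% 2L
  ifelse(sel == 0L, h1, h2)
}

#' Simulate genotypes by gene dropping through the pedigree
#'
#' Founder (sire and dam) haplotypes are drawn from a first-order Markov model
#' with allele frequencies in \code{mafRange} and adjacent-marker correlation
#' \code{ldDecay}; offspring receive one recombinant gamete from each parent.
#'
#' @param structure pedigree data.frame from \code{\link{simulatePedigree}}.
#' @param config the same \code{\link{simConfig}}.
#' @param keepFounders store founder genotype matrices in
#'   \code{metadata()} (needed for transmission checks; costs memory).
#' @return A \linkS4class{GenotypeData} for the offspring, with the pedigree
#'   in \code{colData}.
#' @export
simulateGenotypes <- function(structure, config, keepFounders = TRUE) {
  stopifnot(inherits(config, "SimConfig"), nrow(structure) > 0)
  set.seed(config$seed + 1L)
  m <- config$nSnps
  perChr <- rep(m %/% config$nChromosomes, config$nChromosomes)
  if (m %% config$nChromosomes)
    perChr[seq_len(m %% config$nChromosomes)] <-
      perChr[seq_len(m %% config$nChromosomes)] + 1L
  chrIndex <- rep(seq_len(config$nChromosomes), perChr)
  pos <- unlist(lapply(perChr, function(k) cumsum(sample(500:5000, k,
                                                         replace = TRUE))))
  p <- runif(m, config$mafRange[1], config$mafRange[2])
  flip <- runif(m) < 0.5      # counted allele is minor or major at random
  p[flip] <- 1 - p[flip]

  sires <- sort(unique(structure$sire))
  dams <- sort(unique(structure$dam))
  Hs <- .simHaplotypes(2L * length(sires), p, chrIndex, config$ldDecay)
  Hd <- .simHaplotypes(2L * length(dams), p, chrIndex, config$ldDecay)

  cvec <- if (is.null(config$recombRate)) 1 / perChr[chrIndex]
          else rep(config$recombRate, m)
  cvec <- cvec[-1]
  cvec[diff(chrIndex) != 0] <- 0.5

  n <- nrow(structure)
  si <- match(structure$sire, sires)
  di <- match(structure$dam, dams)
  codes <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    gs <- .gamete(Hs[2L * si[i] - 1L, ], Hs[2L * si[i], ], cvec)
    gd <- .gamete(Hd[2L * di[i] - 1L, ], Hd[2L * di[i], ], cvec)
    codes[i, ] <- gs + gd
  }
  rownames(codes) <- structure$iid
  info <- data.frame(chr = chrIndex, pos = pos,
                     id = paste0("S", chrIndex, "_", pos),
                     ref = "A", alt = "B", stringsAsFactors = FALSE)
  ge <- GenotypeData(codes, info, indIds = structure$iid,
                     indData = structure[, c("sire", "dam", "litter", "batch")])
  if (keepFounders) {
    fS <- Hs[seq(1, nrow(Hs), 2), , drop = FALSE] +
          Hs[seq(2, nrow(Hs), 2), , drop = FALSE]
    fD <- Hd[seq(1, nrow(Hd), 2), , drop = FALSE] +
          Hd[seq(2, nrow(Hd), 2), , drop = FALSE]
    rownames(fS) <- sires; rownames(fD) <- dams
    S4Vectors::metadata(ge)$founderCodes <- rbind(fS, fD)
  }
  ge
}

# dominance-deviation coding at allele frequency p: orthogonal to the
# allele-count regression under Hardy-Weinberg genotype frequencies
.domCode <- function(x, p) {
  q <- 1 - p
  w <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(ncol(x))) {
    w[, k] <- c(-2 * p[k]^2, 2 * p[k] * (1 - p[k]), -2 * (1 - p[k])^2)[x[, k] + 1L]
  }
  w
}

#' Simulate phenotypes with additive, dominance, batch and residual effects
#'
#' Draws QTL positions and effects, builds true breeding values and dominance
#' deviations with the statistical (allele-count-orthogonal) decomposition,
#' rescales them so the realized sample variance ratios equal the target
#' heritabilities, adds batch effects and Gaussian residuals, and optionally
#' rounds to integers.
#'
#' @param genotypes \linkS4class{GenotypeData} from
#'   \code{\link{simulateGenotypes}}.
#' @param structure pedigree data.frame.
#' @param config the same \code{\link{simConfig}}.
#' @return list with \code{phenotypes} (data.frame iid, sire, litter, batch,
#'   y) and \code{truth} (per-individual a, d, g and the QTL table).
#' @export
simulatePhenotypes <- function(genotypes, structure, config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$nQtl > nSnps(genotypes)) stop("nQtl exceeds number of SNPs")
  set.seed(config$seed + 2L)
  X <- genoCodes(genotypes)
  n <- nrow(X)
  pAll <- colMeans(X) / 2
  poly <- which(pAll > 0 & pAll < 1)
  qtl <- sort(sample(poly, min(config$nQtl, length(poly))))
  p <- pAll[qtl]
  sdY <- if (config$discretize) sqrt(max(config$phenoSd^2 - 1 / 12,
                                         0.5 * config$phenoSd^2))
         else config$phenoSd
  varY <- sdY^2

  alpha <- rnorm(length(qtl))
  delta <- rnorm(length(qtl))
  Wq <- sweep(X[, qtl, drop = FALSE], 2, 2 * p)
  a <- drop(Wq %*% alpha)
  d <- drop(.domCode(X[, qtl, drop = FALSE], p) %*% delta)
  scaleTo <- function(v, target) {
    if (target == 0) return(list(v = rep(0, n), f = 0))
    s <- sqrt(target / var(v))
    list(v = v * s, f = s)
  }
  sa <- scaleTo(a, config$h2Add * varY)
  sd_ <- scaleTo(d, config$h2Dom * varY)
  a <- sa$v; d <- sd_$v
  e <- rnorm(n)
  e <- e * sqrt((1 - config$h2Add - config$h2Dom) * varY / var(e))
  bEff <- rnorm(config$nBatches, 0, config$batchSd * sdY)
  bEff <- bEff - mean(bEff)        # deviations from the population mean
  names(bEff) <- sprintf("B%02d", seq_len(config$nBatches))
  y <- config$phenoMean + bEff[structure$batch] + a + d + e
  y <- unname(y)
  if (config$discretize) y <- as.integer(round(y))

  truth <- list(
    a = setNames(a, structure$iid), d = setNames(d, structure$iid),
    g = setNames(a + d, structure$iid),
    qtl = data.frame(id = snpInfo(genotypes)$id[qtl],
                     index = qtl, p = unname(p),
                     addEffect = alpha * sa$f, domEffect = delta * sd_$f,
                     stringsAsFactors = FALSE),
    batchEffects = bEff)
  list(phenotypes = data.frame(structure[, c("iid", "sire", "litter", "batch")],
                               y = y, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running \code{\link{simulatePedigree}},
#' \code{\link{simulateGenotypes}} and \code{\link{simulatePhenotypes}};
#' attaches the phenotype to \code{colData} of the returned genotypes.
#'
#' @param config a \code{\link{simConfig}}.
#' @param keepFounders see \code{\link{simulateGenotypes}}.
#' @return list(genotypes, phenotypes, truth, structure).
#' @export
simulateDataset <- function(config = simConfig(), keepFounders = FALSE) {
  ped <- simulatePedigree(config)
  ge <- simulateGenotypes(ped, config, keepFounders = keepFounders)
  ph <- simulatePhenotypes(ge, ped, config)
  SummarizedExperiment::colData(ge)$y <- ph$phenotypes$y
  list(genotypes = ge, phenotypes = ph$phenotypes, truth = ph$truth,
       structure = ped)
}

#' Write phenotype/covariate and truth tables as TSV
#'
#' @param phenotypes data.frame from \code{\link{simulatePhenotypes}}.
#' @param path output file.
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @param truth truth list from \code{\link{simulatePhenotypes}}.
#' @export
writeTruth <- function(truth, path) {
  df <- data.frame(iid = names(truth$a), a = unname(truth$a),
                   d = unname(truth$d), g = unname(truth$g))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
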