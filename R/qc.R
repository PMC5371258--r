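#' Read genotypes from PLINK binary or VCF
#'
#' PLINK input expects \code{<prefix>.bed/.bim/.fam} with the v1.00 SNP-major
#' bed layout; genotype codes count the bim A1 allele.  VCF input (4.x,
#' optionally gzipped; parsed by \pkg{vcfR}) counts the ALT allele from GT
#' fields; multi-allelic or non-diploid records are skipped with a warning and
#' missing genotypes become NA (mean-imputed downstream by the matrix
#' analyses).
#'
#' @param path file prefix (plink) or file path (vcf).
#' @param format "plink_bed" or "vcf".
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(path, format = c("plink_bed", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_bed") .readPlink(path) else .readVcf(path)
}

.readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + m * ceiling(n / 4))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed PLINK bed magic bytes at offset 0")
  if (raw[3] != as.raw(0x01))
    stop("bed file is not in SNP-major order (mode byte at offset 2)")
  bpm <- ceiling(n / 4)
  if (length(raw) != 3 + m * bpm)
    stop("truncated bed payload: expected ", 3 + m * bpm, " bytes, got ",
         length(raw), " (first missing byte offset ", length(raw), ")")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpm, ncol = m)
  # unpack 2-bit fields; individuals occupy low bits first within each byte
  codes <- matrix(NA_integer_, n, m)
  lut <- .bedLut()
  for (shift in 0:3) {
    if (shift + 1 > n) next
    inds <- seq.int(shift + 1, n, by = 4)
    rows <- (inds - 1L) %/% 4L + 1L
    two <- bitwAnd(bitwShiftR(body[rows, , drop = FALSE], 2L * shift), 3L)
    codes[inds, ] <- lut[two + 1L]
  }
  GenotypeData(codes, data.frame(chr = bim$chr, pos = bim$pos, id = bim$id,
                                 ref = bim$a2, alt = bim$a1),
               indIds = as.character(fam$V2))
}

# bed 2-bit value -> A1 allele count: 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA
.bedLut <- function() c(2L, NA_integer_, 1L, 0L)

#' Write genotypes as PLINK bed/bim/fam
#'
#' SNP-major v1.00 binary layout; codes are written as counts of the bim A1
#' (alt) allele.
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param prefix output file prefix.
#' @return the prefix, invisibly.
#' @export
writePlink <- function(ge, prefix) {
  X <- genoCodes(ge); info <- snpInfo(ge)
  n <- nrow(X); m <- ncol(X)
  fam <- data.frame(fid = indIds(ge), iid = indIds(ge), pat = 0, mat = 0,
                    sex = 0, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = info$chr, id = info$id, cm = 0, pos = info$pos,
                    a1 = info$alt, a2 = info$ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # code -> 2-bit: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  twobit <- c(3L, 2L, 0L)
  vals <- matrix(1L, n, m)
  ok <- !is.na(X)
  vals[ok] <- twobit[X[ok] + 1L]
  bpm <- ceiling(n / 4)
  pad <- bpm * 4 - n
  if (pad) vals <- rbind(vals, matrix(0L, pad, m))
  i1 <- seq(1, bpm * 4, 4)
  bytes <- vals[i1, , drop = FALSE] + 4L * vals[i1 + 1, , drop = FALSE] +
    16L * vals[i1 + 2, , drop = FALSE] + 64L * vals[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

.readVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  keep <- !grepl(",", alt) & !is.na(alt)
  if (any(!keep))
    warning(sum(!keep), " multi-allelic VCF records skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  core <- sub("^([0-9.]([/|][0-9.])?).*$", "\\1", gt)
  codes <- matrix(NA_integer_, nrow(core), ncol(core))
  codes[core %in% c("0/0", "0|0")] <- 0L
  codes[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  codes[core %in% c("1/1", "1|1")] <- 2L
  badPloidy <- !(core %in% c("0/0", "0|0", "0/1", "1/0", "0|1", "1|0",
                             "1/1", "1|1", "./.", ".", ".|."))
  if (any(badPloidy)) {
    warning(sum(badPloidy), " non-diploid/non-biallelic GT fields set to NA")
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- ""
  GenotypeData(t(codes),
               data.frame(chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                          id = ids, ref = fix[, "REF"], alt = alt[keep]),
               indIds = colnames(gt))
}

#' Write genotypes as VCF 4.2
#'
#' GT-only records, unphased; codes are counts of the ALT allele.
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param path output file.
#' @export
writeVcf <- function(ge, path) {
  X <- genoCodes(ge); info <- snpInfo(ge)
  gtmap <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", indIds(ge)), collapse = "\t")), con)
  Xm <- t(X)                               # SNPs x individuals
  gts <- matrix("./.", nrow(Xm), ncol(Xm))
  ok <- !is.na(Xm)
  gts[ok] <- gtmap[Xm[ok] + 1L]
  lines <- paste(info$chr, info$pos, info$id, info$ref, info$alt, ".", "PASS",
                 ".", "GT", apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Per-SNP allele and genotype statistics
#'
#' @param ge a \linkS4class{GenotypeData} (or a codes matrix, individuals x
#'   SNPs).
#' @return data.frame with per-SNP: id, counted-allele frequency \code{p},
#'   \code{maf}, genotype counts \code{n0}, \code{n1}, \code{n2} (codes 0, 1,
#'   2), least-frequent-homozygote frequency \code{homFreq}, and
#'   Hardy-Weinberg chi-square p-value \code{hweP}.
#' @export
alleleStats <- function(ge) {
  X <- if (is(ge, "GenotypeData")) genoCodes(ge) else as.matrix(ge)
  n0 <- colSums(X == 0L, na.rm = TRUE)
  n1 <- colSums(X == 1L, na.rm = TRUE)
  n2 <- colSums(X == 2L, na.rm = TRUE)
  nn <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * nn)
  maf <- pmin(p, 1 - p)
  homFreq <- pmin(n0, n2) / nn
  ids <- if (is(ge, "GenotypeData")) snpInfo(ge)$id else colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(X)))
  data.frame(
    id = ids,
    p = p, maf = maf, n0 = n0, n1 = n1, n2 = n2, n = nn,
    homFreq = homFreq, hweP = hweTest(n2, n1, n0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium test
#'
#' Continuity-free Pearson chi-square with 1 df on expected genotype counts
#' under the allele frequency estimated from the sample.  Monomorphic SNPs
#' return p = 1 by convention.  Vectorized over SNPs.
#'
#' @param nAA,nAa,naa genotype counts.
#' @param midp use the exact conditional test with the mid-p correction
#'   instead of the chi-square.
#' @return p-values in [0, 1].
#' @export
hweTest <- function(nAA, nAa, naa, midp = FALSE) {
  if (midp) return(mapply(.hweExactMidp, nAA, nAa, naa))
  n <- nAA + nAa + naa
  if (any(n == 0)) stop("total genotype count must be positive")
  p <- (2 * nAA + nAa) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(nAA, nAa, naa)
  chi <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  out <- pchisq(chi, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

# exact HWE: condition on allele counts, enumerate heterozygote counts
.hweExactMidp <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  rare <- min(nA, 2 * n - nA)
  het <- seq(rare %% 2, rare, by = 2)
  logpr <- lgamma(n + 1) - lgamma((rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - rare - het) / 2 + 1) + het * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  pr <- exp(logpr - max(logpr))
  pr <- pr / sum(pr)
  obs <- min(nAa, rare)
  pobs <- pr[match(obs, het)]
  min(1, sum(pr[pr <= pobs + 1e-12]) - 0.5 * pobs)
}

#' Filter SNPs by MAF, minimum homozygote frequency and HWE
#'
#' Keeps a SNP iff MAF > \code{mafMin}, the frequency of the least frequent
#' homozygous genotype is >= \code{homMin}, and the HWE p-value is >=
#' \code{hweMin} (defaults follow a GBS QC protocol for commercial pig data:
#' MAF > 0.05, homozygote frequency >= 0.01, HWE p >= 1e-6).
#'
#' @param ge a \linkS4class{GenotypeData}.
#' @param mafMin,homMin,hweMin thresholds.
#' @param hweMethod "chisq" (default) or "midp".
#' @return list(genotypes = filtered GenotypeData, report = FilterReport list
#'   with per-rule failure counts, surviving count and per-SNP pass flags).
#' @export
filterSnps <- function(ge, mafMin = 0.05, homMin = 0.01, hweMin = 1e-6,
                       hweMethod = c("chisq", "midp")) {
  hweMethod <- match.arg(hweMethod)
  st <- alleleStats(ge)
  if (hweMethod == "midp") st$hweP <- hweTest(st$n2, st$n1, st$n0, midp = TRUE)
  passMaf <- st$maf > mafMin
  passHom <- st$homFreq >= homMin
  passHwe <- st$hweP >= hweMin
  keep <- passMaf & passHom & passHwe
  report <- list(
    input = nrow(st), surviving = sum(keep),
    failMaf = sum(!passMaf), failHom = sum(!passHom), failHwe = sum(!passHwe),
    failAny = sum(!keep),
    flags = data.frame(id = st$id, passMaf = passMaf, passHom = passHom,
                       passHwe = passHwe, pass = keep,
                       stringsAsFactors = FALSE),
    thresholds = c(mafMin = mafMin, homMin = homMin, hweMin = hweMin))
  class(report) <- "FilterReport"
  list(genotypes = ge[keep, ], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", x$input, "SNPs in,", x$surviving, "surviving\n")
  cat("  failed MAF:", x$failMaf, " failed hom-freq:", x$failHom,
      " failed HWE:", x$failHwe, "\n")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report FilterReport from \code{\link{filterSnps}}.
#' @param path output file.
#' @export
writeFilterReport <- function(report, path) {
  write.table(report$flags, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing genotype codes
#'
#' Replaces NA codes by 2p per SNP (twice the counted-allele frequency of the
#' observed genotypes); returns a numeric matrix.
#'
#' @param ge a \linkS4class{GenotypeData} or codes matrix.
#' @return numeric matrix, individuals x SNPs.
#' @export
imputedCodes <- function(ge) {
  X <- if (is(ge, "GenotypeData")) genoCodes(ge) else as.matrix(ge)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}
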