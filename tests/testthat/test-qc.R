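test_that("PLINK bed round trip preserves codes, ids and order", {
  ge <- toyGeno(n = 4, m = 3)
  prefix <- file.path(tempdir(), "rt4")
  writePlink(ge, prefix)
  back <- readGenotypes(prefix, "plink_bed")
  expect_equal(unname(genoCodes(back)), unname(genoCodes(ge)))
  expect_equal(snpInfo(back)$id, snpInfo(ge)$id)
  expect_equal(indIds(back), indIds(ge))
})

test_that("bed packing of the final partial byte matches a brute-force bit decoder", {
  for (n in 4:9) {           # covers every n %% 4 case
    set.seed(n)
    codes <- matrix(sample(c(0:2, NA), n * 5, TRUE, prob = c(.3, .3, .3, .1)),
                    n, 5)
    info <- data.frame(chr = 1, pos = 1:5 * 10, id = paste0("x", 1:5))
    ge <- GenotypeData(codes, info, indIds = paste0("I", seq_len(n)))
    prefix <- file.path(tempdir(), paste0("bits", n))
    writePlink(ge, prefix)
    expect_equal(unname(genoCodes(readGenotypes(prefix, "plink_bed"))),
                 bruteBedDecode(paste0(prefix, ".bed"), n, 5),
                 info = paste("n =", n))
  }
})

test_that("malformed bed files raise format errors", {
  prefix <- file.path(tempdir(), "bad")
  ge <- toyGeno(n = 4, m = 3)
  writePlink(ge, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(raw[1:(length(raw) - 1)], paste0(prefix, ".bed"))
  expect_error(readGenotypes(prefix, "plink_bed"), "truncated")
  writeBin(c(as.raw(0), raw[-1]), paste0(prefix, ".bed"))
  expect_error(readGenotypes(prefix, "plink_bed"), "magic")
})

test_that("VCF genotypes map to alt-allele counts and round-trip", {
  vcf <- file.path(tempdir(), "small.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "1|1", "0/0", sep = "\t"),
    paste("1", "300", "v3", "C", "T,G", ".", "PASS", ".", "GT",
          "0/0", "0/2", "0/0", sep = "\t")), vcf)
  expect_warning(ge <- readGenotypes(vcf, "vcf"), "multi-allelic")
  expect_equal(nSnps(ge), 2)
  expect_equal(unname(genoCodes(ge)[, "v1"]), c(0L, 1L, 2L))
  expect_equal(unname(genoCodes(ge)[, "v2"]), c(NA_integer_, 2L, 0L))

  ge2 <- toyGeno(n = 5, m = 4)
  out <- file.path(tempdir(), "rt.vcf")
  writeVcf(ge2, out)
  expect_equal(unname(genoCodes(readGenotypes(out, "vcf"))),
               unname(genoCodes(ge2)))
})

test_that("allele statistics match a brute-force tally", {
  expect_equal(alleleStats(matrix(rep(c(2, 1, 0), c(25, 50, 25))))$p, 0.5)
  expect_equal(alleleStats(matrix(rep(c(2, 1, 0), c(25, 50, 25))))$maf, 0.5)
  st <- alleleStats(matrix(rep(c(2, 1, 0), c(0, 10, 90))))
  expect_equal(st$p, 0.05)
  expect_equal(st$maf, 0.05)
  expect_equal(st$homFreq, 0)

  set.seed(33)
  x <- sample(0:2, 1000, TRUE, prob = c(.5, .3, .2))
  st <- alleleStats(matrix(x))
  expect_equal(st$n0, sum(x == 0))
  expect_equal(st$n1, sum(x == 1))
  expect_equal(st$n2, sum(x == 2))
  expect_equal(st$p, (2 * sum(x == 2) + sum(x == 1)) / 2000)
})

test_that("HWE chi-square reproduces hand-computed values", {
  expect_equal(hweTest(25, 50, 25), 1)
  # (30,40,30): E = (25,50,25), chi2 = 25/25 + 100/50 + 25/25 = 4
  expect_equal(hweTest(30, 40, 30), pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(hweTest(30, 40, 30), 4), 0.0455)
  # (50,0,50): chi2 = 100
  expect_equal(hweTest(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hweTest(50, 0, 50), 1e-6)
  # monomorphic convention
  expect_equal(hweTest(100, 0, 0), 1)
  # vectorized
  expect_equal(hweTest(c(25, 30), c(50, 40), c(25, 30)),
               c(1, pchisq(4, 1, lower.tail = FALSE)))
  # mid-p exact agrees with chi-square in a large balanced sample
  expect_lt(abs(hweTest(250, 500, 250, midp = TRUE) - 1), 0.2)
})

test_that("SNP filters apply the MAF/homozygote/HWE rules jointly", {
  # panel engineered to the stats {MAF, hom-freq, HWE}:
  # snp1 fails MAF, snp3 fails HWE, snp4 fails hom-freq, snps 2 and 5 pass
  n <- 200
  mk <- function(n0, n1, n2) rep(c(0L, 1L, 2L), c(n0, n1, n2))
  codes <- cbind(
    mk(184, 16, 0),    # maf .04, hom 0
    mk(162, 36, 2),    # maf .10, hom .01, HWE ok
    mk(120, 0, 80),    # maf .40 but zero hets -> HWE p << 1e-6
    mk(100, 100, 0),   # maf .25, hom 0
    mk(50, 100, 50))   # maf .50, hom .25
  ge <- GenotypeData(codes, data.frame(chr = 1, pos = 1:5 * 10,
                                       id = paste0("m", 1:5)),
                     indIds = paste0("I", 1:n))
  res <- filterSnps(ge)
  expect_equal(res$report$surviving, 2)
  expect_equal(snpInfo(res$genotypes)$id, c("m2", "m5"))
  expect_equal(res$report$input, 5)
  expect_equal(res$report$surviving + res$report$failAny, res$report$input)

  # monomorphic panel: nothing survives
  mono <- GenotypeData(matrix(1L, 10, 3) * 0L,
                       data.frame(chr = 1, pos = 1:3, id = paste0("z", 1:3)),
                       indIds = paste0("I", 1:10))
  expect_equal(filterSnps(mono)$report$surviving, 0)

  # zero thresholds keep everything
  expect_equal(filterSnps(ge, 0, 0, 0)$report$surviving, 5)
})

test_that("filtering is idempotent", {
  sim <- sharedSim()
  f1 <- filterSnps(sim$genotypes)
  f2 <- filterSnps(f1$genotypes)
  expect_equal(nSnps(f2$genotypes), nSnps(f1$genotypes))
  expect_identical(genoCodes(f2$genotypes), genoCodes(f1$genotypes))
})

test_that("mean imputation fills NA with 2p", {
  codes <- matrix(c(0L, 2L, NA, 1L, 1L, 1L), 3, 2)
  X <- imputedCodes(codes)
  expect_equal(X[3, 1], 1)       # 2p = 2 * (0+2)/(2*2)
  expect_equal(X[, 2], c(1, 1, 1))
})
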