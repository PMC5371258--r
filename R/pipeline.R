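#' Run the full analysis pipeline
#'
#' Orchestrates, from a single configuration, the stages: data acquisition
#' (simulation or files), SNP QC, relationship matrices + MDS, GREML
#' heritability, single-SNP GWAS by the selected methods, significant-SNP
#' set, SNP-set contribution analysis, and k-fold cross-validation.  All
#' tabular outputs are written as TSV with headers, stage summaries as JSON,
#' and a manifest (file checksums, per-stage row/SNP counts and wall-clock)
#' is written and returned.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{sim}{arguments for \code{\link{simConfig}} (exclusive with
#'       \code{genotypes}).}
#'     \item{genotypes, format, phenotypes}{input paths for
#'       \code{\link{readGenotypes}} and a phenotype TSV with columns iid,
#'       sire, litter, batch, y (exclusive with \code{sim}).}
#'     \item{qc}{list(mafMin, homMin, hweMin).}
#'     \item{nMds}{MDS dimensions for the LS scans (default 35, capped at
#'       n - 1).}
#'     \item{methods}{subset of c("gls", "ls-add", "ls-geno").}
#'     \item{folds}{CV folds (default 10; 0 skips CV).}
#'     \item{includeDominance}{fit dominance (default TRUE).}
#'     \item{sets}{named list of SNP sets (ids or region strings) for the
#'       contribution analysis; the significant-SNP union is always
#'       analyzed when non-empty.}
#'     \item{seed}{integer seed.}
#'     \item{out}{output directory.}
#'   }
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$sim) && !is.null(config$genotypes))
    stop("config must supply exactly one of sim or genotypes")
  if (is.null(config$sim) && is.null(config$genotypes))
    stop("config must supply one of sim or genotypes")
  out <- config$out
  if (is.null(out)) stop("config$out (output directory) is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  folds <- if (is.null(config$folds)) 10L else as.integer(config$folds)
  nMds <- if (is.null(config$nMds)) 35L else as.integer(config$nMds)
  methods <- if (is.null(config$methods)) c("gls", "ls-add", "ls-geno")
             else config$methods
  incDom <- if (is.null(config$includeDominance)) TRUE
            else isTRUE(config$includeDominance)

  manifest <- list(package = as.character(utils::packageVersion("partherit")),
                   seed = seed, stages = list(), files = list())
  clock <- function(expr) {
    t0 <- proc.time()[3]
    v <- expr
    list(value = v, secs = round(proc.time()[3] - t0, 2))
  }
  emit <- function(name, path) {
    manifest$files[[name]] <<- list(path = path,
                                    md5 = unname(tools::md5sum(path)))
  }

  ## stage: data
  st <- clock({
    if (!is.null(config$sim)) {
      sc <- do.call(simConfig, c(config$sim, list(seed = seed)))
      simulateDataset(sc)
    } else {
      ge <- readGenotypes(config$genotypes,
                          format = if (is.null(config$format)) "plink_bed"
                                   else config$format)
      ph <- read.table(config$phenotypes, header = TRUE,
                       stringsAsFactors = FALSE)
      ph <- ph[match(indIds(ge), ph$iid), ]
      if (anyNA(ph$y)) stop("phenotypes missing for some genotyped ids")
      list(genotypes = ge, phenotypes = ph, truth = NULL, structure = ph)
    }
  })
  data <- st$value
  writePhenotypes(data$phenotypes, file.path(out, "phenotypes.tsv"))
  emit("phenotypes", file.path(out, "phenotypes.tsv"))
  manifest$stages$data <- list(secs = st$secs, n = nInds(data$genotypes),
                               snps = nSnps(data$genotypes))

  ## stage: qc
  qcArgs <- config$qc
  st <- clock(do.call(filterSnps, c(list(data$genotypes),
                                    qcArgs[names(qcArgs) %in%
                                           c("mafMin", "homMin", "hweMin")])))
  ge <- st$value$genotypes
  writeFilterReport(st$value$report, file.path(out, "filter_report.tsv"))
  emit("filter_report", file.path(out, "filter_report.tsv"))
  manifest$stages$qc <- list(secs = st$secs, surviving = nSnps(ge),
                             removed = st$value$report$failAny)
  y <- data$phenotypes$y
  batch <- data$phenotypes$batch

  ## stage: relationship matrices + MDS
  st <- clock({
    A <- additiveGRM(ge)
    D <- if (incDom) dominanceGRM(ge) else NULL
    S <- ibsMatrix(ge)
    nM <- min(nMds, nInds(ge) - 2L)
    mds <- mdsComponents(S, d = nM)
    list(A = A, D = D, mds = mds, nM = ncol(mds$coords))
  })
  A <- st$value$A; D <- st$value$D; mds <- st$value$mds
  nMdsUse <- min(nMds, st$value$nM)
  writeGRM(A, file.path(out, "additive"))
  emit("grm_additive", file.path(out, "additive.grm.txt"))
  utils::write.table(
    data.frame(iid = indIds(ge), mds$coords),
    file.path(out, "mds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  emit("mds", file.path(out, "mds.tsv"))
  manifest$stages$relationship <- list(secs = st$secs, mdsDims = nMdsUse)

  ## stage: GREML
  spec <- mixedModelSpec(y, A = A, D = D, batch = batch, ids = indIds(ge))
  st <- clock(fitGreml(spec))
  vc <- st$value
  h2 <- heritabilities(vc)
  jsonlite::write_json(
    list(sigma = as.list(vc@sigma), se = as.list(vc@se),
         h2 = as.list(h2@h2), h2se = as.list(h2@se),
         logLik = vc@logLik, iterations = vc@iterations),
    file.path(out, "greml.json"), auto_unbox = TRUE, digits = NA)
  emit("greml", file.path(out, "greml.json"))
  manifest$stages$greml <- list(secs = st$secs,
                                h2 = round(unclass(h2@h2), 4))

  ## stage: GWAS
  scans <- list()
  st <- clock({
    if ("gls" %in% methods)
      scans$gls <- glsFamilyScan(ge, y, batch = batch)
    if ("ls-add" %in% methods)
      scans$lsAdd <- lsMdsScan(ge, y, mds = mds, nMds = nMdsUse,
                               batch = batch, genotypic = FALSE)
    if ("ls-geno" %in% methods)
      scans$lsGeno <- lsMdsScan(ge, y, mds = mds, nMds = nMdsUse,
                                batch = batch, genotypic = TRUE)
    scans
  })
  scans <- st$value
  for (nm in names(scans)) {
    writeScan(scans[[nm]], file.path(out, paste0("scan_", nm, ".tsv")))
    emit(paste0("scan_", nm), file.path(out, paste0("scan_", nm, ".tsv")))
  }
  jsonlite::write_json(
    lapply(scans, function(s) list(method = s@method, lambda = s@lambda,
                                   bonferroni = s@threshold)),
    file.path(out, "gwas_summary.json"), auto_unbox = TRUE, digits = NA)
  emit("gwas_summary", file.path(out, "gwas_summary.json"))
  manifest$stages$gwas <- list(secs = st$secs,
                               lambda = lapply(scans, function(s)
                                 round(s@lambda, 3)))

  ## stage: significant set
  sig <- NULL
  if (length(scans)) {
    sig <- significantSnps(unname(scans))
    utils::write.table(sig$flags, file.path(out, "significant_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("significant_snps", file.path(out, "significant_snps.tsv"))
    manifest$stages$significant <- list(union = length(sig$union))
  }

  ## stage: contribution (optional; failures do not abort later stages)
  sets <- config$sets
  if (!is.null(sig) && length(sig$union) > 0 &&
      length(sig$union) < nSnps(ge) / 2)
    sets <- c(sets, list(significant = sig$union))
  if (length(sets)) {
    st <- clock({
      reports <- list()
      for (nm in names(sets)) {
        reports[[nm]] <- tryCatch(
          partialHeritability(ge, y, sets[[nm]], batch = batch,
                              includeDominance = incDom, setName = nm),
          error = function(e) {
            warning("contribution analysis for set '", nm, "' failed: ",
                    conditionMessage(e))
            NULL
          })
      }
      reports
    })
    reports <- Filter(Negate(is.null), st$value)
    jsonlite::write_json(
      lapply(reports, function(r) list(
        method = r@method, setSize = r@setSize, full = as.list(r@full),
        reduced = as.list(r@reduced),
        contribution = as.list(r@contribution))),
      file.path(out, "contribution.json"), auto_unbox = TRUE, digits = NA)
    emit("contribution", file.path(out, "contribution.json"))
    manifest$stages$contribution <- list(secs = st$secs,
                                         sets = names(reports))
  }

  ## stage: cross-validation
  if (folds > 0) {
    st <- clock(crossValidate(spec, makeFolds(length(y), k = folds,
                                              seed = seed)))
    acc <- st$value
    utils::write.table(acc@perFold, file.path(out, "cv_perfold.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(acc@pooled, file.path(out, "cv_pooled.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("cv_perfold", file.path(out, "cv_perfold.tsv"))
    emit("cv_pooled", file.path(out, "cv_pooled.tsv"))
    manifest$stages$cv <- list(secs = st$secs,
                               observed = round(acc@pooled$observed, 4))
  }

  manifest$finished <- TRUE
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
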