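#' Pipeline configuration
#'
#' Collects every tunable of the screen in one validated list: the
#' pre-filter thresholds (E-value 1e-44, identity 43%), the similarity
#' cutoff of the criterion filter, the HMM match-column gap threshold,
#' the pattern span slack, the HMM bit threshold (NA = calibrate from
#' the training family), the neighborhood window and the master RNG
#' seed. Serializable to a plain-text DCF file.
#'
#' @param eMax,idMin pre-filter thresholds.
#' @param similarityCutoff minimum substitution score scored "similar".
#' @param gapThreshold HMM match-column rule.
#' @param spanSlack pattern placement slack (residues).
#' @param bitThreshold HMM hit threshold in bits; NA to calibrate.
#' @param windowGenes neighborhood window (genes each side).
#' @param seed master seed; all pipeline randomness flows from it.
#' @param fixturesDir,outDir input and report directories.
#' @return a validated config list of class "amdPipelineConfig".
#' @export
pipelineConfig <- function(eMax = 1e-44, idMin = 43, similarityCutoff = 1,
                           gapThreshold = 0.5, spanSlack = 5L,
                           bitThreshold = NA_real_, windowGenes = 10L,
                           seed = 1L, fixturesDir = "fixtures",
                           outDir = "reports") {
  cfg <- list(eMax = as.numeric(eMax), idMin = as.numeric(idMin),
              similarityCutoff = as.numeric(similarityCutoff),
              gapThreshold = as.numeric(gapThreshold),
              spanSlack = as.integer(spanSlack),
              bitThreshold = as.numeric(bitThreshold),
              windowGenes = as.integer(windowGenes),
              seed = as.integer(seed),
              fixturesDir = fixturesDir, outDir = outDir)
  class(cfg) <- "amdPipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' @describeIn pipelineConfig validate a config; errors before any
#'   computation when a threshold is out of its documented range.
#' @param config a config list.
#' @export
validatePipelineConfig <- function(config) {
  with(config, {
    if (!(eMax > 0)) stop("eMax must be positive")
    if (idMin < 0 || idMin > 100) stop("idMin must be in [0, 100]")
    if (gapThreshold <= 0 || gapThreshold > 1) stop("gapThreshold must be in (0, 1]")
    if (spanSlack < 0) stop("spanSlack must be non-negative")
    if (windowGenes <= 0) stop("windowGenes must be positive")
  })
  invisible(config)
}

#' @describeIn pipelineConfig write the config as plain-text DCF.
#' @param path file path.
#' @export
writePipelineConfig <- function(config, path) {
  m <- t(as.matrix(vapply(unclass(config), function(v)
    format(v, digits = 17, scientific = TRUE), "")))
  rownames(m) <- NULL
  colnames(m) <- names(config)
  write.dcf(m, path)
  invisible(path)
}

#' @describeIn pipelineConfig read a config written by
#'   [writePipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  m <- read.dcf(path)
  get1 <- function(key) unname(m[1L, key])
  num1 <- function(key) {
    v <- get1(key)
    if (identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  pipelineConfig(eMax = num1("eMax"),
                 idMin = num1("idMin"),
                 similarityCutoff = num1("similarityCutoff"),
                 gapThreshold = num1("gapThreshold"),
                 spanSlack = as.integer(num1("spanSlack")),
                 bitThreshold = num1("bitThreshold"),
                 windowGenes = as.integer(num1("windowGenes")),
                 seed = as.integer(num1("seed")),
                 fixturesDir = get1("fixturesDir"),
                 outDir = get1("outDir"))
}

.stage_log <- function(stage, n, what) {
  message(sprintf("[amdscreen] %s: %d %s", stage, n, what))
}

.write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' fixtures -> screen -> build-hmm/hmmscan -> classify -> summarize.
#' Generates the synthetic fixture set when `fixturesDir` does not yet
#' contain one, screens every sequence against the reference, builds a
#' profile HMM from the family alignment and scores all sequences
#' against it, assigns the cluster-benchmark candidates to the eight
#' clusters, and tabulates the metadata. Each stage logs its counts to
#' stderr; reports are TSV files under `outDir`.
#'
#' @param config an [pipelineConfig()] list.
#' @param withHmm score all screened sequences with the HMM (default
#'   TRUE).
#' @return (invisibly) list with report paths and per-stage counts.
#' @export
runPipeline <- function(config = pipelineConfig(), withHmm = TRUE) {
  validatePipelineConfig(config)
  fx <- config$fixturesDir
  if (!file.exists(file.path(fx, "reference.faa"))) {
    makeFixtures(fx, seed = config$seed)
    .stage_log("make-fixtures", length(list.files(fx, recursive = TRUE)), "files")
  }
  for (f in c("reference.faa", "family.faa", "family.afa"))
    if (!file.exists(file.path(fx, f))) stop("missing input: ", file.path(fx, f))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  ref <- readProteinFasta(file.path(fx, "reference.faa"))
  fam <- readProteinFasta(file.path(fx, "family.faa"))
  rac <- readProteinFasta(file.path(fx, "racemase_decoys.faa"))
  unr <- readProteinFasta(file.path(fx, "unrelated_decoys.faa"))
  aln <- readProteinAlignment(file.path(fx, "family.afa"), "afa")

  hmm <- buildProfileHMM(aln, gapThreshold = config$gapThreshold)
  hmmPath <- file.path(config$outDir, "amdase.hmm")
  writeProfileHMM(hmm, hmmPath)
  logo <- hmmLogo(hmm, aln, gapThreshold = config$gapThreshold)
  logoPath <- .write_report(logo, file.path(config$outDir, "logo.tsv"))
  .stage_log("build-hmm", hmm@nMatch, "match states")

  bitThr <- config$bitThreshold
  if (is.na(bitThr)) bitThr <- calibrateBitThreshold(hmm, fam)

  all_seqs <- c(fam, rac, unr)
  verdicts <- screenSet(all_seqs, reference = ref,
                        eMax = config$eMax, idMin = config$idMin,
                        similarityCutoff = config$similarityCutoff,
                        spanSlack = config$spanSlack,
                        hmm = if (withHmm) hmm else NULL)
  screenReport <- verdictTable(verdicts)
  screenPath <- .write_report(screenReport,
                              file.path(config$outDir, "screen_report.tsv"))
  .stage_log("screen", nrow(screenReport), "candidates screened")

  hmmReport <- data.frame(id = names(all_seqs),
                          bits = if (withHmm) screenReport$hmm_bits
                                 else vapply(seq_along(all_seqs), function(i)
                                   hmmForward(hmm, all_seqs[[i]]), 0),
                          stringsAsFactors = FALSE)
  hmmReport$hit <- hmmReport$bits >= bitThr
  hmmPathTsv <- .write_report(hmmReport, file.path(config$outDir, "hmm_report.tsv"))
  .stage_log("hmmscan", sum(hmmReport$hit), "hits")

  clusterPath <- NULL
  nClustered <- 0L
  anchorsTsv <- file.path(fx, "anchors.tsv")
  if (file.exists(anchorsTsv)) {
    anchors <- utils::read.delim(anchorsTsv, stringsAsFactors = FALSE)
    ancSeqs <- readProteinFasta(file.path(fx, "anchors.faa"))
    candSeqs <- readProteinFasta(file.path(fx, "cluster_candidates.faa"))
    d <- identityDistanceMatrix(c(ancSeqs, candSeqs))
    tr <- njTree(d)
    rows <- lapply(names(candSeqs), function(id) {
      tag <- sub("^cand_", "", id)
      nbFile <- file.path(fx, "neighborhoods", paste0(tag, ".gff3"))
      fams <- if (file.exists(nbFile)) {
        nb <- readNeighborhood(nbFile, "gff3",
                               focalLocus = .focal_locus_of(nbFile),
                               windowGenes = config$windowGenes)
        detectFamily(nb)$families
      } else "none"
      asg <- assignCluster(id, tr, fams, anchors)
      data.frame(id = id, coarse = asg$coarse, cluster = asg$cluster,
                 nearest_anchor = asg$nearestAnchor,
                 distance = asg$distance,
                 families = paste(fams, collapse = ","),
                 note = asg$note, stringsAsFactors = FALSE)
    })
    clusterReport <- do.call(rbind, rows)
    clusterPath <- .write_report(clusterReport,
                                 file.path(config$outDir, "cluster_report.tsv"))
    nClustered <- nrow(clusterReport)
    ape::write.tree(tr, file.path(config$outDir, "tree.nwk"))
    .stage_log("classify", nClustered, "candidates assigned")
  }

  summaryPath <- NULL
  metaTsv <- file.path(fx, "metadata.tsv")
  if (file.exists(metaTsv)) {
    meta <- readStrainMetadata(metaTsv)
    s <- summarizeStrains(meta)
    sumDf <- rbind(
      data.frame(section = "genes_per_class", key = names(s$genesPerClass),
                 value = as.numeric(s$genesPerClass)),
      data.frame(section = "genera_per_class", key = names(s$generaPerClass),
                 value = as.numeric(s$generaPerClass)),
      data.frame(section = "strains_per_genus", key = names(s$strainsPerGenus),
                 value = as.numeric(s$strainsPerGenus)),
      data.frame(section = "habitat_pct", key = names(s$habitatPct),
                 value = as.numeric(s$habitatPct)))
    summaryPath <- .write_report(sumDf, file.path(config$outDir, "summary.tsv"))
    .stage_log("summarize", nrow(meta), "strains tabulated")
  }

  invisible(list(reports = list(screen = screenPath, hmm = hmmPathTsv,
                                model = hmmPath, logo = logoPath,
                                clusters = clusterPath, summary = summaryPath),
                 counts = list(screened = nrow(screenReport),
                               hmmHits = sum(hmmReport$hit),
                               clustered = nClustered),
                 bitThreshold = bitThr,
                 verdicts = verdicts))
}

# first locus tag annotated as an arylmalonate decarboxylase in a GFF3
.focal_locus_of <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  hit <- which(grepl("arylmalonate", gr$product, ignore.case = TRUE))
  if (!length(hit)) stop("no amd gene in ", path)
  gr$locus_tag[hit[1L]]
}
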