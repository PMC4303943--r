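## End-to-end pipeline on synthetic data: generate inputs, write and re-read
## them through the io layer, classify SNP origins, delimit segments, run
## the DE stage, annotate candidate SNPs, and nominate candidate genes.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    out_dir = "introscan-run",
    with_sequence = TRUE,
    min_qual = 100,
    bin_width = 1e6,
    genome_bin_width = 1e7,
    sift_deleterious_max = 0.05,
    genome = list(
      chromosomes = list(list(name = "chr1", length = 2.9e8),
                         list(name = "chr2", length = 5e7)),
      coding_fraction = 0.05,
      snp_density = 15),
    truth_segments = list(
      list(chrom = "chr1", start = 8.9e7, end = 9.7e7),
      list(chrom = "chr1", start = 1.04e8, end = 1.051e8),
      list(chrom = "chr1", start = 1.78e8, end = 2.1e8),
      list(chrom = "chr1", start = 2.34e8, end = 2.74e8)),
    breeding = list(n_backcrosses = 8L, bp_per_cM = 2e6,
                    simulate = FALSE,
                    markers = list(list(chrom = "chr1", pos = 1.9e8))),
    observation = list(coverage_dropout = 0.2, error_rate = 0.005),
    detection = list(min_support = 3, donor_fraction = 0.8,
                     max_gap_bins = 2),
    de = list(min_mean_count = 10, padj_threshold = 0.1,
              lfc_threshold = 1.0, relaxed_pvalue_threshold = 0.05),
    counts = list(n_genes = 2000L, n_samples_per_group = c(3L, 3L),
                  nb_mean_range = c(20, 500), nb_dispersion = 0.1,
                  de_fraction = 0.1, de_log2fc = c(-2, -1, 1, 2)))
}

#' Pipeline configuration emulating the study design
#'
#' Four donor-origin truth segments on a 290-Mbp focal chromosome
#' (cumulative 81.1 Mbp), one clean second chromosome, 15 divergent coding
#' SNPs per Mbp, QUAL filter at 100, RNA-Seq observation with 20\% coverage
#' dropout and 0.5\% allele error, and an N = 8 backcross breeding model.
#'
#' @param seed integer seed for every stochastic stage.
#' @return a validated configuration list.
#' @export
studyLikeConfig <- function(seed = 1L) {
  cfg <- pipelineDefaults()
  cfg$seed <- as.integer(seed)
  validatePipelineConfig(cfg)
}

#' Read and validate a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' \code{\link{studyLikeConfig}}.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a configuration list to validate/complete.
#' @export
validatePipelineConfig <- function(cfg) {
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (grp in c("genome", "breeding", "observation", "detection", "de",
                "counts")) {
    if (!is.null(cfg[[grp]])) {
      bad <- setdiff(names(cfg[[grp]]), names(defaults[[grp]]))
      if (length(bad))
        stop("unknown key(s) in '", grp, "': ",
             paste(bad, collapse = ", "))
      defaults[[grp]][names(cfg[[grp]])] <- cfg[[grp]]
    }
  }
  top <- setdiff(names(defaults),
                 c("genome", "breeding", "observation", "detection", "de",
                   "counts"))
  for (k in intersect(names(cfg), top)) defaults[[k]] <- cfg[[k]]
  if (defaults$bin_width <= 0 || defaults$genome_bin_width <= 0)
    stop("bin widths must be positive")
  if (defaults$min_qual < 0) stop("min_qual must be non-negative")
  if (defaults$genome$snp_density < 0) stop("snp_density must be >= 0")
  defaults
}

chromLengthsOf <- function(cfg) {
  ch <- cfg$genome$chromosomes
  stats::setNames(vapply(ch, function(x) as.numeric(x$length), numeric(1)),
                  vapply(ch, function(x) as.character(x$name),
                         character(1)))
}

truthSegmentsOf <- function(cfg) {
  if (is.null(cfg$truth_segments) || length(cfg$truth_segments) == 0L)
    return(NULL)
  do.call(rbind, lapply(cfg$truth_segments, function(s)
    data.frame(chrom = s$chrom, start = as.numeric(s$start),
               end = as.numeric(s$end))))
}

#' Run the full congenic-mapping pipeline on synthetic data
#'
#' Simulates parental genomes and a congenic mosaic (fixed truth segments,
#' or marker-selected backcrossing when \code{breeding$simulate} is TRUE),
#' observes all three strains through the RNA-Seq noise model, writes the
#' VCF/coverage/count inputs to \code{outDir}, re-reads them through the io
#' layer, and executes origin classification, segment detection, the DE
#' stage, consequence annotation and candidate nomination. All stages are
#' reproducible from the configuration plus its seed.
#'
#' @param cfg configuration list from \code{\link{studyLikeConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param outDir output directory (defaults to \code{cfg$out_dir}).
#' @param stages \code{"all"} for the full analysis, \code{"simulate"} to
#'   stop after the synthetic inputs (VCFs, coverage tables, counts) have
#'   been written.
#' @return invisibly, a list with the mosaic, origin calls, segments,
#'   genome scan, DE results, consequence records and the candidate set
#'   (input-generation results only under \code{stages = "simulate"}).
#' @export
runPipeline <- function(cfg = studyLikeConfig(), outDir = cfg$out_dir,
                        stages = c("all", "simulate")) {
  stages <- match.arg(stages)
  cfg <- validatePipelineConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  cat(sprintf("introscan run %s\n", format(Sys.time())), file = logFile)
  cat(yaml::as.yaml(cfg), file = file.path(outDir, "config.yaml"))
  logLine("parameters: seed=%d, min_qual=%g, bin_width=%g",
          cfg$seed, cfg$min_qual, cfg$bin_width)

  chromLengths <- chromLengthsOf(cfg)
  spec <- genomeSpec(
    data.frame(name = names(chromLengths), length = unname(chromLengths)),
    codingFraction = cfg$genome$coding_fraction,
    snpDensity = cfg$genome$snp_density, seed = cfg$seed)
  logLine("simulating parental genomes (%d chromosome(s), %.0f Mbp)",
          length(chromLengths), sum(chromLengths) / 1e6)
  sim <- simulateParentalGenomes(spec,
                                 withSequence = isTRUE(cfg$with_sequence))

  bm <- breedingModel(
    data.frame(name = names(chromLengths), length = unname(chromLengths)),
    nBackcrosses = cfg$breeding$n_backcrosses,
    bpPerCM = cfg$breeding$bp_per_cM,
    selectedMarkers = do.call(rbind, lapply(cfg$breeding$markers,
      function(m) data.frame(chrom = m$chrom, pos = as.numeric(m$pos)))))
  truth <- truthSegmentsOf(cfg)
  if (isTRUE(cfg$breeding$simulate) || is.null(truth)) {
    logLine("simulating %d marker-selected backcross generation(s)",
            cfg$breeding$n_backcrosses)
    mosaic <- simulateBackcross(bm, seed = cfg$seed + 1L)
  } else {
    mosaic <- mosaicFromSegments(chromLengths, truth)
  }

  obs <- observationModel(
    coverageDropout = cfg$observation$coverage_dropout,
    errorRate = cfg$observation$error_rate)
  strains <- list(
    donor = pureMosaic(chromLengths, "donor"),
    recipient = pureMosaic(chromLengths, "recipient"),
    congenic = mosaic)
  observations <- list()
  for (s in names(strains)) {
    o <- observeVariants(strains[[s]], sim$sites, obs, s,
                         seed = cfg$seed + match(s, names(strains)))
    writeStrainVcf(o, file.path(outDir, paste0(s, ".vcf")),
                   seed = cfg$seed)
    writeCoveredSites(o, file.path(outDir, paste0(s, "_covered.tsv")))
    observations[[s]] <- o
  }

  nUse <- min(cfg$counts$n_genes, length(sim$genes))
  csim <- simulateCounts(countSimSpec(
    nGenes = nUse,
    nSamplesPerGroup = unlist(cfg$counts$n_samples_per_group),
    nbMeanRange = unlist(cfg$counts$nb_mean_range),
    nbDispersion = cfg$counts$nb_dispersion,
    deFraction = cfg$counts$de_fraction,
    deLog2fc = unlist(cfg$counts$de_log2fc),
    seed = cfg$seed + 10L))
  modelIds <- mcols(geneRanges(sim$genes))$gene_id[
    round(seq(1L, length(sim$genes), length.out = nUse))]
  rownames(csim$counts) <- modelIds
  csim$truth$gene_id <- modelIds
  writeCountMatrix(csim$counts, file.path(outDir, "counts.tsv"))
  if (stages == "simulate") {
    logLine("synthetic inputs written; analysis stages skipped")
    return(invisible(list(config = cfg, mosaic = mosaic,
                          observations = observations,
                          countTruth = csim$truth)))
  }

  tables <- lapply(names(strains), function(s)
    readStrainVcf(file.path(outDir, paste0(s, ".vcf")), strainLabel = s,
                  minQual = cfg$min_qual))
  names(tables) <- names(strains)
  covered <- readCoveredSites(file.path(outDir, "congenic_covered.tsv"))

  specific <- strainSpecificSites(
    tables$donor, tables$recipient,
    donorCovered = readCoveredSites(file.path(outDir,
                                              "donor_covered.tsv")),
    recipientCovered = readCoveredSites(file.path(outDir,
                                                  "recipient_covered.tsv")))
  calls <- classifyCongenicOrigin(tables$congenic, specific$donorSpecific,
                                  specific$recipientSpecific, covered)
  seqlevels(calls) <- names(chromLengths)
  seqlengths(calls) <- chromLengths
  bins <- binOriginCalls(calls, binWidth = cfg$bin_width,
                         chromLengths = chromLengths)
  segs <- detectSegments(bins, minSupport = cfg$detection$min_support,
                         donorFraction = cfg$detection$donor_fraction,
                         maxGapBins = cfg$detection$max_gap_bins)
  scan <- genomeScan(calls, chromLengths,
                     binWidth = cfg$genome_bin_width,
                     minSupport = cfg$detection$min_support,
                     donorFraction = cfg$detection$donor_fraction,
                     maxGapBins = cfg$detection$max_gap_bins)
  utils::write.table(segs, file.path(outDir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  flank <- expectedFlanking(bm)
  logLine("detected %d segment(s), cumulative %.1f Mbp; expected flank %.1f cM/side",
          nrow(segs), cumulativeLength(segs), flank$per_side_cM)

  deCfg <- deConfig(minMeanCount = cfg$de$min_mean_count,
                    padjThreshold = cfg$de$padj_threshold,
                    lfcThreshold = cfg$de$lfc_threshold,
                    relaxedPvalueThreshold =
                      cfg$de$relaxed_pvalue_threshold)
  counts <- readCountMatrix(file.path(outDir, "counts.tsv"))
  deRes <- nbTest(counts, csim$groups, deCfg)
  deSet <- deFilter(deRes, "strict", deCfg)
  utils::write.table(deRes, file.path(outDir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLine("DE stage: %d gene(s) tested, %d in the strict DE set",
          sum(deRes$status == "tested"), nrow(deSet))

  candSnps <- candidateSnpFilter(tables$donor, tables$recipient,
                                 tables$congenic, segs)
  consequences <- if (isTRUE(cfg$with_sequence) && length(candSnps)) {
    annotateCandidates(candSnps, sim$genes)
  } else annotateEmpty()
  utils::write.table(consequences,
                     file.path(outDir, "consequences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  deInLocus <- crossReference(deSet$gene_id, segs, sim$genes)
  candidates <- nominateCandidates(consequences, deInLocus,
                                   strainLabel = "congenic",
                                   gms = sim$genes)
  writeCandidateReport(candidates, outDir)
  logLine("candidates: %d polymorphic, %d DE-in-locus, %d overlap",
          length(candidates$polymorphic), length(candidates$deInLocus),
          length(candidates$overlap))

  invisible(list(config = cfg, mosaic = mosaic, originCalls = calls,
                 bins = bins, segments = segs, scan = scan,
                 flanking = flank, deResults = deRes, deSet = deSet,
                 candidateSnps = candSnps, consequences = consequences,
                 candidates = candidates))
}
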