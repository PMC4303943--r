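## Canned simulation experiments at the study's conditions, shared by the
## test suite and the acceptance script so the conditions are defined once.

#' Default donor-origin truth segments of the simulated congenic chromosome
#'
#' Four donor segments (89.0-97.0, 104.0-105.1, 178.0-210.0 and
#' 234.0-274.0 Mbp) on a 290-Mbp focal chromosome; cumulative 81.1 Mbp.
#'
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (half-open bp).
#' @export
defaultTruthSegments <- function() {
  data.frame(chrom = "chr1",
             start = c(89, 104, 178, 234) * 1e6,
             end = c(97, 105.1, 210, 274) * 1e6)
}

#' Segment-recovery experiment on simulated congenic genomes
#'
#' Simulates divergent parental variant sets at \code{snpDensity} sites per
#' Mbp, imposes the truth donor segments on the focal chromosome, observes
#' the congenic strain through the RNA-Seq noise model
#' (\code{coverageDropout}, \code{errorRate}), classifies SNP origins
#' against the parental tables, bins at \code{binWidth} and runs segment
#' detection with its defaults; the parental variant sets themselves enter
#' as fully observed call tables, the congenic observation being the noisy
#' step under study. Gene models are built once and reused across
#' replicates; divergent-site placement and observation are redrawn every
#' replicate.
#'
#' @param nReps number of independent replicates.
#' @param seed integer seed governing the whole experiment.
#' @param truthSegments data.frame of donor truth segments
#'   (\code{\link{defaultTruthSegments}}).
#' @param chromLength focal chromosome length (bp).
#' @param snpDensity divergent coding sites per Mbp.
#' @param coverageDropout,errorRate congenic observation noise.
#' @param binWidth bin width for the focal chromosome.
#' @param minQual QUAL filter applied when reading the call tables.
#' @return list with \code{cumulative} (Mbp per replicate),
#'   \code{truthCumulative}, and \code{segments} (detected segments of the
#'   first replicate).
#' @export
segmentRecoveryExperiment <- function(nReps = 1L, seed = 1L,
                                      truthSegments =
                                        defaultTruthSegments(),
                                      chromLength = 2.9e8,
                                      snpDensity = 15,
                                      coverageDropout = 0.2,
                                      errorRate = 0.005,
                                      binWidth = 1e6, minQual = 100) {
  chromLengths <- c(chr1 = chromLength)
  names(chromLengths) <- unique(truthSegments$chrom)[1L]
  mosaic <- mosaicFromSegments(chromLengths, truthSegments)
  donorPure <- pureMosaic(chromLengths, "donor")
  recipPure <- pureMosaic(chromLengths, "recipient")
  noiseless <- observationModel(coverageDropout = 0, errorRate = 0)
  noisy <- observationModel(coverageDropout = coverageDropout,
                            errorRate = errorRate)
  baseSpec <- genomeSpec(
    data.frame(name = names(chromLengths), length = unname(chromLengths)),
    snpDensity = snpDensity, seed = seed)
  genes <- simulateGeneModels2(baseSpec)
  qualFilter <- function(o) {
    g <- variantCalls(o)
    g <- g[mcols(g)$qual >= minQual]
    new("StrainVariants", calls = g, strain = strain(o))
  }
  cum <- numeric(nReps)
  firstSegs <- NULL
  for (r in seq_len(nReps)) {
    spec <- genomeSpec(
      data.frame(name = names(chromLengths),
                 length = unname(chromLengths)),
      snpDensity = snpDensity, seed = seed + r)
    sim <- simulateParentalGenomes(spec, genes = genes)
    donorTab <- qualFilter(observeVariants(donorPure, sim$sites,
                                           noiseless, "donor",
                                           seed = seed + 3L * r))
    recipTab <- qualFilter(observeVariants(recipPure, sim$sites,
                                           noiseless, "recipient",
                                           seed = seed + 3L * r + 1L))
    congObs <- observeVariants(mosaic, sim$sites, noisy, "congenic",
                               seed = seed + 3L * r + 2L)
    sp <- strainSpecificSites(donorTab, recipTab)
    calls <- classifyCongenicOrigin(qualFilter(congObs),
                                    sp$donorSpecific,
                                    sp$recipientSpecific,
                                    coveredSites(congObs))
    segs <- detectSegments(binOriginCalls(calls, binWidth, chromLengths))
    cum[r] <- cumulativeLength(segs)
    if (r == 1L) firstSegs <- segs
  }
  list(cumulative = cum, truthCumulative = cumulativeLength(truthSegments),
       segments = firstSegs)
}

## seed-free wrapper so gene models can be prebuilt from a spec whose seed
## is already set by the caller
simulateGeneModels2 <- function(spec) {
  set.seed(spec@seed)
  simulateGeneModels(spec)
}
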