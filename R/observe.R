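## RNA-Seq variant observation: restricts SNP visibility to "expressed"
## (covered) sites and injects base-call errors, so that absence of a record
## is ambiguous exactly as it is in real congenic RNA-Seq data.

#' Variant calls plus the covered-site evidence for one strain
#'
#' @slot calls a \linkS4class{StrainVariants} of emitted non-reference
#'   records (the VCF body).
#' @slot covered a \code{GRanges} of all truth sites that were observed
#'   (expressed with sufficient coverage), whether or not a variant record
#'   was emitted. This is what licenses "absence of a record means the
#'   reference allele" during origin classification.
#' @export
setClass("StrainObservation",
  representation(calls = "StrainVariants", covered = "GRanges"))

#' @rdname accessors
setMethod("variantCalls", "StrainObservation", function(x) x@calls@calls)

#' @rdname accessors
setMethod("strain", "StrainObservation", function(x) x@calls@strain)

#' @rdname accessors
#' @export
setGeneric("coveredSites", function(x) standardGeneric("coveredSites"))

#' @rdname accessors
setMethod("coveredSites", "StrainObservation", function(x) x@covered)

setMethod("show", "StrainObservation", function(object) {
  cat(sprintf(paste0("StrainObservation ('%s'): %d variant record(s), ",
                     "%d covered site(s)\n"),
              object@calls@strain, length(object@calls@calls),
              length(object@covered)))
})

#' Observe truth variant sites through the RNA-Seq noise model
#'
#' For every truth site, the strain's true allele follows the mosaic origin
#' at that position (donor allele on donor background, recipient allele
#' otherwise). The site is dropped with probability \code{coverageDropout};
#' otherwise the reported allele is the true one, or, with probability
#' \code{errorRate}, the site's other allele. Non-reference reports become
#' VCF-style records with a QUAL drawn from the true-call or error-call
#' distribution of \code{obs}.
#'
#' @param mosaic a \linkS4class{GenomeMosaic} for the observed strain (use
#'   \code{\link{pureMosaic}} for a parental strain).
#' @param sites truth site table from
#'   \code{\link{simulateParentalGenomes}} (mcols \code{ref}, \code{donor},
#'   \code{recipient}); the mosaic must cover every site.
#' @param obs an \linkS4class{ObservationModel}.
#' @param strainLabel label recorded on the emitted calls.
#' @param seed integer RNG seed.
#' @return a \linkS4class{StrainObservation}.
#' @export
observeVariants <- function(mosaic, sites, obs, strainLabel, seed = 1L) {
  stopifnot(is(mosaic, "GenomeMosaic"), is(obs, "ObservationModel"))
  set.seed(as.integer(seed))
  n <- length(sites)
  emptyCalls <- strainVariants(character(0), integer(0), character(0),
                               character(0), numeric(0),
                               strain = strainLabel)
  if (n == 0L)
    return(new("StrainObservation", calls = emptyCalls,
               covered = GRanges()))
  origin <- originAtPositions(mosaic, sites)
  if (anyNA(origin))
    stop("mosaic does not cover all truth positions")
  ref <- mcols(sites)$ref
  trueAllele <- ifelse(origin == "donor", mcols(sites)$donor,
                       mcols(sites)$recipient)
  otherAllele <- ifelse(trueAllele == mcols(sites)$donor,
                        mcols(sites)$recipient, mcols(sites)$donor)
  # at shared-alt sites donor == recipient allele; an error then reports ref
  otherAllele <- ifelse(otherAllele == trueAllele, ref, otherAllele)
  observed <- stats::runif(n) >= obs@coverageDropout
  isError <- stats::runif(n) < obs@errorRate
  reported <- ifelse(isError, otherAllele, trueAllele)
  qual <- ifelse(isError,
                 stats::runif(n, obs@errorQualRange[1L],
                              obs@errorQualRange[2L]),
                 obs@trueQualMin + stats::rexp(n, 1 / obs@trueQualSpread))
  emit <- observed & reported != ref
  covered <- granges(sites[observed])
  if (!any(emit))
    return(new("StrainObservation", calls = emptyCalls, covered = covered))
  calls <- strainVariants(as.character(seqnames(sites))[emit],
                          start(sites)[emit], ref[emit], reported[emit],
                          round(qual[emit], 2), strain = strainLabel,
                          seqlengths = seqlengths(sites))
  new("StrainObservation", calls = calls, covered = covered)
}

#' Mosaic origin at query positions
#'
#' @param mosaic a \linkS4class{GenomeMosaic}.
#' @param at a \code{GRanges} of positions.
#' @return character vector of \code{"donor"}/\code{"recipient"} (NA where
#'   uncovered).
#' @export
originAtPositions <- function(mosaic, at) {
  seg <- mosaicSegments(mosaic)
  # disjoint seqlevels simply mean no overlap, not a malformed query
  hits <- suppressWarnings(findOverlaps(granges(at), seg,
                                        ignore.strand = TRUE))
  out <- rep(NA_character_, length(at))
  out[queryHits(hits)] <- as.character(mcols(seg)$origin[subjectHits(hits)])
  out
}
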