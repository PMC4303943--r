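#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<- findOverlaps granges sort tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame Rle queryHits subjectHits runValue
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement subseq translate GENETIC_CODE
NULL

VALID_BASES <- c("A", "C", "G", "T")

## ---- StrainVariants --------------------------------------------------------

#' Quality-filtered single-nucleotide variant calls for one strain
#'
#' Wraps a \link[GenomicRanges]{GRanges} of width-1 sites with metadata
#' columns \code{ref}, \code{alt} and \code{qual}, together with the strain
#' label. Only biallelic single-nucleotide records are allowed; indels and
#' identical ref/alt pairs are rejected by the validity method.
#'
#' @slot calls a \code{GRanges} of width-1 positions with mcols \code{ref},
#'   \code{alt} (single bases) and \code{qual} (non-negative numeric).
#' @slot strain single character label, e.g. \code{"donor"}.
#' @export
setClass("StrainVariants",
  representation(calls = "GRanges", strain = "character"))

setValidity("StrainVariants", function(object) {
  gr <- object@calls
  msg <- character()
  if (length(object@strain) != 1L || is.na(object@strain))
    msg <- c(msg, "'strain' must be a single label")
  need <- c("ref", "alt", "qual")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("calls must carry mcols", paste(need, collapse = ", ")))
  if (length(gr)) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "all calls must be width-1 (SNVs only)")
    ref <- as.character(mcols(gr)$ref)
    alt <- as.character(mcols(gr)$alt)
    if (!all(ref %in% VALID_BASES) || !all(alt %in% VALID_BASES))
      msg <- c(msg, "ref/alt must be single bases A/C/G/T (indels rejected)")
    if (any(ref == alt))
      msg <- c(msg, "ref and alt alleles must differ")
    if (any(mcols(gr)$qual < 0, na.rm = TRUE))
      msg <- c(msg, "qual must be non-negative")
    if (any(start(gr) < 1L))
      msg <- c(msg, "positions must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StrainVariants object
#'
#' @param chrom,pos,ref,alt,qual vectors describing the calls (\code{pos} is
#'   1-based), recycled to common length.
#' @param strain strain label.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return a \linkS4class{StrainVariants} object, sorted by position.
#' @export
#' @examples
#' strainVariants("chr1", c(100, 250), ref = c("A", "G"),
#'                alt = c("G", "T"), qual = c(130, 155), strain = "donor")
strainVariants <- function(chrom, pos, ref, alt, qual, strain,
                           seqlengths = NULL) {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(gr)$ref <- toupper(as.character(ref))
  mcols(gr)$alt <- toupper(as.character(alt))
  mcols(gr)$qual <- as.numeric(qual)
  if (!is.null(seqlengths))
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  new("StrainVariants", calls = GenomicRanges::sort(gr), strain = strain)
}

## ---- GenomeMosaic ----------------------------------------------------------

#' Donor/recipient ancestry mosaic of a (congenic) genome
#'
#' Ordered ancestry segments tiling each chromosome without gap or overlap;
#' adjacent segments always switch origin. This is the ground-truth object the
#' breeding simulator produces and against which origin classification is
#' scored.
#'
#' @slot segments a \code{GRanges} (1-based, inclusive) with mcol
#'   \code{origin}, a factor with levels \code{donor}, \code{recipient};
#'   seqlengths must be set.
#' @export
setClass("GenomeMosaic", representation(segments = "GRanges"))

setValidity("GenomeMosaic", function(object) {
  gr <- object@segments
  if (!"origin" %in% colnames(mcols(gr)))
    return("segments must carry an 'origin' mcol")
  org <- mcols(gr)$origin
  if (!is.factor(org) || !identical(levels(org), c("donor", "recipient")))
    return("origin must be a factor with levels donor, recipient")
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    return("seqlengths must be set for every chromosome")
  msg <- character()
  for (chr in seqlevels(gr)) {
    g <- gr[seqnames(gr) == chr]
    if (length(g) == 0L) {
      msg <- c(msg, sprintf("chromosome %s has no segments", chr))
      next
    }
    o <- order(start(g))
    g <- g[o]
    if (start(g)[1L] != 1L || end(g)[length(g)] != sl[[chr]])
      msg <- c(msg, sprintf("%s: segments do not span [1, seqlength]", chr))
    if (length(g) > 1L) {
      if (any(start(g)[-1L] != end(g)[-length(g)] + 1L))
        msg <- c(msg, sprintf("%s: segments overlap or leave gaps", chr))
      oo <- as.character(mcols(g)$origin)
      if (any(oo[-1L] == oo[-length(g)]))
        msg <- c(msg, sprintf("%s: adjacent segments share an origin", chr))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeMosaic from explicit donor segments
#'
#' All positions not covered by \code{donorSegments} are recipient-origin.
#' Donor segment boundaries are given as 0-based half-open bp intervals
#' (the convention used for bin and segment edges throughout the package);
#' they are converted to 1-based inclusive ranges internally.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param donorSegments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open bp), or NULL for a pure-recipient genome.
#' @return a \linkS4class{GenomeMosaic}.
#' @export
#' @examples
#' mosaicFromSegments(c(chr1 = 3e6),
#'   data.frame(chrom = "chr1", start = 1e6, end = 2e6))
mosaicFromSegments <- function(chromLengths, donorSegments = NULL) {
  stopifnot(!is.null(names(chromLengths)), all(chromLengths > 0))
  pieces <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    ds <- donorSegments[donorSegments$chrom == chr, , drop = FALSE]
    if (is.null(ds) || nrow(ds) == 0L) {
      return(data.frame(chrom = chr, start = 1, end = len,
                        origin = "recipient"))
    }
    ds <- ds[order(ds$start), , drop = FALSE]
    if (any(ds$start < 0) || any(ds$end > len) || any(ds$end <= ds$start))
      stop("donor segments outside chromosome or empty on ", chr)
    if (any(ds$start[-1L] < ds$end[-nrow(ds)]))
      stop("donor segments overlap on ", chr)
    starts <- ds$start + 1   # to 1-based inclusive
    ends <- ds$end
    out <- data.frame(chrom = chr, start = starts, end = ends,
                      origin = "donor")
    gaps_start <- c(1, ends + 1)
    gaps_end <- c(starts - 1, len)
    keep <- gaps_end >= gaps_start
    if (any(keep))
      out <- rbind(out, data.frame(chrom = chr,
                                   start = gaps_start[keep],
                                   end = gaps_end[keep],
                                   origin = "recipient"))
    out[order(out$start), , drop = FALSE]
  })
  df <- do.call(rbind, pieces)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                seqinfo = Seqinfo(names(chromLengths),
                                  unname(chromLengths)))
  mcols(gr)$origin <- factor(df$origin, levels = c("donor", "recipient"))
  new("GenomeMosaic", segments = gr)
}

## ---- GeneModelSet ----------------------------------------------------------

#' A set of gene models with CDS intervals and coding sequences
#'
#' @slot genes \code{GRanges}, one range per gene spanning its CDS footprint,
#'   with mcols \code{gene_id} and \code{symbol}.
#' @slot cds \code{GRangesList} named by gene_id; per gene, CDS intervals
#'   (1-based inclusive) ordered 5' to 3' in transcript orientation.
#' @slot codingSeq \code{DNAStringSet} named by gene_id; the spliced coding
#'   sequence in coding orientation (minus-strand genes already
#'   reverse-complemented).
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", cds = "GRangesList",
                 codingSeq = "DNAStringSet"))

setValidity("GeneModelSet", function(object) {
  ids <- mcols(object@genes)$gene_id
  msg <- character()
  if (is.null(ids) || is.null(mcols(object@genes)$symbol))
    return("genes must carry mcols gene_id and symbol")
  if (anyDuplicated(ids)) msg <- c(msg, "gene_id values must be unique")
  if (!identical(names(object@cds), as.character(ids)) ||
      !identical(names(object@codingSeq), as.character(ids)))
    msg <- c(msg, "cds and codingSeq must be named by gene_id, same order")
  tot <- sum(width(object@cds))
  if (any(tot %% 3L != 0L))
    msg <- c(msg, "total CDS length must be a multiple of 3")
  if (!identical(unname(Biostrings::width(object@codingSeq)),
                 unname(as.integer(tot))))
    msg <- c(msg, "coding sequence length must equal total CDS length")
  red <- sum(width(GenomicRanges::reduce(object@cds)))
  if (any(red != tot))
    msg <- c(msg, "CDS intervals within a gene must not overlap")
  if (length(msg)) msg else TRUE
})

## ---- simulation parameter bags --------------------------------------------

#' Specification of a pair of divergent parental genomes
#'
#' Describes the simulated chromosomes, how much of each is coding, and how
#' many coding sites diverge between the two inbred parents.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{length} (bp).
#' @slot codingFraction fraction of each chromosome inside simulated CDS.
#' @slot snpDensity expected donor-vs-recipient divergent coding sites per
#'   Mbp of chromosome.
#' @slot donorAltFraction fraction of divergent sites at which the donor (not
#'   the recipient) carries the non-reference allele.
#' @slot sharedFraction density of shared-alt sites (both strains carry the
#'   same non-reference allele) relative to \code{snpDensity}; these are
#'   uninformative and exercise the shared-site exclusion path.
#' @slot seed integer RNG seed.
#' @export
setClass("GenomeSpec",
  representation(chromosomes = "data.frame", codingFraction = "numeric",
                 snpDensity = "numeric", donorAltFraction = "numeric",
                 sharedFraction = "numeric", seed = "integer"))

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  msg <- character()
  if (!all(c("name", "length") %in% names(ch)) || nrow(ch) == 0L)
    return("chromosomes must be a non-empty data.frame(name, length)")
  if (any(ch$length <= 0))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (object@codingFraction <= 0 || object@codingFraction > 1)
    msg <- c(msg, "codingFraction must be in (0, 1]")
  if (object@snpDensity < 0) msg <- c(msg, "snpDensity must be >= 0")
  if (object@donorAltFraction < 0 || object@donorAltFraction > 1)
    msg <- c(msg, "donorAltFraction must be in [0, 1]")
  if (object@sharedFraction < 0)
    msg <- c(msg, "sharedFraction must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param chromosomes data.frame with columns \code{name} and \code{length}.
#' @param codingFraction,snpDensity,donorAltFraction,sharedFraction,seed see
#'   slot documentation in \linkS4class{GenomeSpec}.
#' @return a \linkS4class{GenomeSpec}.
#' @rdname GenomeSpec-class
#' @export
genomeSpec <- function(chromosomes, codingFraction = 0.05, snpDensity = 15,
                       donorAltFraction = 0.5, sharedFraction = 0.1,
                       seed = 1L) {
  new("GenomeSpec", chromosomes = as.data.frame(chromosomes),
      codingFraction = codingFraction, snpDensity = snpDensity,
      donorAltFraction = donorAltFraction, sharedFraction = sharedFraction,
      seed = as.integer(seed))
}

#' Marker-assisted backcross breeding model
#'
#' Haldane (no-interference) crossover model: per meiosis the number of
#' crossovers on a chromosome is Poisson with mean equal to its genetic
#' length in Morgans and breakpoints are uniform on the cM scale. A uniform
#' conversion of \code{bpPerCM} base pairs per centimorgan links the genetic
#' and physical maps.
#'
#' @slot nBackcrosses number of backcross generations N.
#' @slot bpPerCM base pairs per centimorgan (default 2e6).
#' @slot chromosomes data.frame(name, length) of physical lengths in bp.
#' @slot geneticLengths named numeric, per-chromosome map length in cM.
#' @slot selectedMarkers \code{GRanges} of width-1 marker positions whose
#'   donor allele is selected for at every generation.
#' @export
setClass("BreedingModel",
  representation(nBackcrosses = "integer", bpPerCM = "numeric",
                 chromosomes = "data.frame", geneticLengths = "numeric",
                 selectedMarkers = "GRanges"))

setValidity("BreedingModel", function(object) {
  msg <- character()
  if (object@nBackcrosses < 1L) msg <- c(msg, "nBackcrosses must be >= 1")
  if (object@bpPerCM <= 0) msg <- c(msg, "bpPerCM must be > 0")
  ch <- object@chromosomes
  gl <- object@geneticLengths
  if (!identical(sort(names(gl)), sort(as.character(ch$name))))
    return("geneticLengths must be named by chromosome")
  expect <- ch$length / object@bpPerCM
  if (any(abs(gl[as.character(ch$name)] - expect) > 1e-6 * expect))
    msg <- c(msg, "geneticLengths inconsistent with physical lengths via bpPerCM")
  mk <- object@selectedMarkers
  if (length(mk)) {
    lens <- stats::setNames(ch$length, ch$name)
    bad <- !(as.character(seqnames(mk)) %in% names(lens)) |
      start(mk) < 1L | start(mk) > lens[as.character(seqnames(mk))]
    if (any(bad))
      msg <- c(msg, "selected marker outside its chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' @param chromosomes data.frame(name, length in bp).
#' @param nBackcrosses,bpPerCM see slots.
#' @param selectedMarkers data.frame(chrom, pos) of marker positions under
#'   donor-allele selection.
#' @param geneticLengths optional named cM lengths; derived from the physical
#'   lengths via \code{bpPerCM} when NULL.
#' @return a \linkS4class{BreedingModel}.
#' @rdname BreedingModel-class
#' @export
breedingModel <- function(chromosomes, nBackcrosses = 8L, bpPerCM = 2e6,
                          selectedMarkers = NULL, geneticLengths = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  if (is.null(geneticLengths))
    geneticLengths <- stats::setNames(chromosomes$length / bpPerCM,
                                      chromosomes$name)
  if (is.null(selectedMarkers)) {
    mk <- GRanges()
  } else {
    mk <- GRanges(selectedMarkers$chrom,
                  IRanges(as.integer(selectedMarkers$pos), width = 1L))
  }
  new("BreedingModel", nBackcrosses = as.integer(nBackcrosses),
      bpPerCM = bpPerCM, chromosomes = chromosomes,
      geneticLengths = geneticLengths, selectedMarkers = mk)
}

#' RNA-Seq variant observation model
#'
#' Models how RNA-Seq restricts SNP visibility: an informative site is
#' unobserved (not expressed / insufficient coverage) with probability
#' \code{coverageDropout}; an observed site is reported with the wrong allele
#' with probability \code{errorRate}. True calls receive QUAL
#' \code{trueQualMin} + Exponential(mean \code{trueQualSpread}); erroneous
#' calls receive QUAL uniform on \code{errorQualRange}, so a QUAL filter at
#' 100 removes part but not all of the error calls.
#'
#' @slot coverageDropout probability in [0, 1].
#' @slot errorRate probability in [0, 1].
#' @slot trueQualMin,trueQualSpread,errorQualRange QUAL samplers.
#' @export
setClass("ObservationModel",
  representation(coverageDropout = "numeric", errorRate = "numeric",
                 trueQualMin = "numeric", trueQualSpread = "numeric",
                 errorQualRange = "numeric"))

setValidity("ObservationModel", function(object) {
  msg <- character()
  if (object@coverageDropout < 0 || object@coverageDropout > 1)
    msg <- c(msg, "coverageDropout must be in [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must be in [0, 1]")
  if (length(object@errorQualRange) != 2L ||
      diff(object@errorQualRange) < 0)
    msg <- c(msg, "errorQualRange must be c(lo, hi) with lo <= hi")
  if (length(msg)) msg else TRUE
})

#' @param coverageDropout,errorRate,trueQualMin,trueQualSpread,errorQualRange
#'   see slot documentation in \linkS4class{ObservationModel}.
#' @return an \linkS4class{ObservationModel}.
#' @rdname ObservationModel-class
#' @export
observationModel <- function(coverageDropout = 0.2, errorRate = 0.005,
                             trueQualMin = 100, trueQualSpread = 40,
                             errorQualRange = c(30, 150)) {
  new("ObservationModel", coverageDropout = coverageDropout,
      errorRate = errorRate, trueQualMin = trueQualMin,
      trueQualSpread = trueQualSpread, errorQualRange = errorQualRange)
}

#' Negative-binomial count-matrix simulation spec
#'
#' @slot nGenes,nSamplesPerGroup dimensions (two groups).
#' @slot nbMeanRange range of per-gene base means, drawn log-uniformly.
#' @slot nbDispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @slot deFraction fraction of genes that are differentially expressed.
#' @slot deLog2fc candidate log2 fold-changes assigned to DE genes.
#' @slot seed integer RNG seed.
#' @export
setClass("CountSimSpec",
  representation(nGenes = "integer", nSamplesPerGroup = "integer",
                 nbMeanRange = "numeric", nbDispersion = "numeric",
                 deFraction = "numeric", deLog2fc = "numeric",
                 seed = "integer"))

setValidity("CountSimSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@nSamplesPerGroup) != 2L ||
      any(object@nSamplesPerGroup < 1L))
    msg <- c(msg, "nSamplesPerGroup must be two values >= 1")
  if (object@nbDispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,nSamplesPerGroup,nbMeanRange,nbDispersion,deFraction,deLog2fc,seed
#'   see slot documentation in \linkS4class{CountSimSpec}.
#' @return a \linkS4class{CountSimSpec}.
#' @rdname CountSimSpec-class
#' @export
countSimSpec <- function(nGenes = 2000L, nSamplesPerGroup = c(3L, 3L),
                         nbMeanRange = c(20, 500), nbDispersion = 0.1,
                         deFraction = 0.1, deLog2fc = c(-2, -1, 1, 2),
                         seed = 1L) {
  if (length(nSamplesPerGroup) == 1L)
    nSamplesPerGroup <- rep(nSamplesPerGroup, 2L)
  new("CountSimSpec", nGenes = as.integer(nGenes),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      nbMeanRange = nbMeanRange, nbDispersion = nbDispersion,
      deFraction = deFraction, deLog2fc = deLog2fc, seed = as.integer(seed))
}
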