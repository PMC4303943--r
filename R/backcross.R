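## Marker-assisted backcross simulation under the Haldane model. Ancestry is
## haploid-trackable because both parents are inbred: the F1 contributes one
## whole-chromosome donor haplotype, and every generation crosses the current
## donor-bearing chromosome against a pure recipient homolog.

#' Simulate N marker-selected backcross generations
#'
#' Starting from an F1 whose tracked haplotype is entirely donor-origin, each
#' generation draws a Poisson number of crossovers (mean = genetic length in
#' Morgans) with breakpoints uniform on the cM scale, forms a gamete by
#' alternating between the current haplotype and a pure recipient homolog,
#' and retains (by rejection) a gamete carrying the donor allele at every
#' selected marker of the chromosome. Chromosomes without selected markers
#' undergo unselected transmission, so their residual donor content halves
#' in expectation each generation.
#'
#' @param model a \linkS4class{BreedingModel}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GenomeMosaic} of the final congenic genome.
#' @export
#' @examples
#' bm <- breedingModel(data.frame(name = "chr1", length = 2e8),
#'                     nBackcrosses = 8,
#'                     selectedMarkers = data.frame(chrom = "chr1", pos = 1e8))
#' simulateBackcross(bm, seed = 1)
simulateBackcross <- function(model, seed = 1L) {
  stopifnot(is(model, "BreedingModel"))
  validObject(model)
  set.seed(as.integer(seed))
  chroms <- model@chromosomes
  segs <- lapply(seq_len(nrow(chroms)), function(i) {
    chr <- as.character(chroms$name[i])
    lenBp <- chroms$length[i]
    lenCM <- model@geneticLengths[[chr]]
    mk <- model@selectedMarkers
    mkCM <- start(mk[seqnames(mk) == chr]) / model@bpPerCM
    hap <- list(breaks = c(0, lenCM), origin = "donor")  # F1 haplotype
    for (g in seq_len(model@nBackcrosses))
      hap <- transmitGamete(hap, lenCM, mkCM)
    hapToBp(hap, chr, lenBp, model@bpPerCM)
  })
  gr <- do.call(c, segs)
  seqlevels(gr) <- as.character(chroms$name)
  seqlengths(gr) <- stats::setNames(chroms$length, chroms$name)
  new("GenomeMosaic", segments = gr)
}

## One meiosis with rejection on the selected markers. 'hap' is a step
## function on [0, lenCM]: breaks (length k+1) and origin per interval.
transmitGamete <- function(hap, lenCM, markersCM, maxTries = 100000L) {
  for (try in seq_len(maxTries)) {
    k <- stats::rpois(1L, lenCM / 100)
    xpts <- if (k > 0L) sort(stats::runif(k, 0, lenCM)) else numeric(0)
    fromCurrent <- sample(c(TRUE, FALSE), 1L)
    gam <- combineHomologs(hap, xpts, fromCurrent, lenCM)
    if (length(markersCM) == 0L ||
        all(originAtCM(gam, markersCM) == "donor"))
      return(gam)
  }
  stop("marker-selected gamete not obtained after ", maxTries, " meioses")
}

## Gamete origin at position t: current haplotype's origin where the gamete
## reads the current homolog, recipient elsewhere. Homolog identity
## alternates at each crossover point.
combineHomologs <- function(hap, xpts, startFromCurrent, lenCM) {
  breaks <- sort(unique(c(0, lenCM, xpts, hap$breaks)))
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  nCross <- findInterval(mids, xpts)
  useCurrent <- if (startFromCurrent) nCross %% 2L == 0L else
    nCross %% 2L == 1L
  curOrigin <- hap$origin[findInterval(mids, hap$breaks,
                                       rightmost.closed = TRUE)]
  origin <- ifelse(useCurrent, curOrigin, "recipient")
  keep <- c(TRUE, origin[-1L] != origin[-length(origin)])
  list(breaks = c(breaks[-length(breaks)][keep], lenCM),
       origin = origin[keep])
}

originAtCM <- function(hap, atCM) {
  hap$origin[findInterval(atCM, hap$breaks, rightmost.closed = TRUE)]
}

## cM step function -> 1-based inclusive bp segments tiling the chromosome.
## Rounding to bp can empty a sliver interval, so equal-origin neighbours are
## re-merged afterwards.
hapToBp <- function(hap, chr, lenBp, bpPerCM) {
  cuts <- round(hap$breaks / hap$breaks[length(hap$breaks)] * lenBp)
  ok <- diff(cuts) > 0
  starts <- cuts[-length(cuts)][ok] + 1
  ends <- cuts[-1L][ok]
  origin <- hap$origin[ok]
  isRunStart <- c(TRUE, origin[-1L] != origin[-length(origin)])
  runEnds <- c(which(isRunStart)[-1L] - 1L, length(origin))
  gr <- GRanges(chr, IRanges(starts[isRunStart], ends[runEnds]))
  mcols(gr)$origin <- factor(origin[isRunStart],
                             levels = c("donor", "recipient"))
  gr
}

#' Monte-Carlo distribution of donor flanking lengths around a marker
#'
#' Replays the marker-selected breeding of \code{\link{simulateBackcross}}
#' on the chromosome of the first selected marker, working directly on the
#' cM scale (the same meiosis engine, without materializing bp mosaics),
#' and records the one-sided donor flanking lengths around the marker in
#' each replicate. Useful for checking the simulator against the 100/N cM
#' closed form at Monte-Carlo scale.
#'
#' @param model a \linkS4class{BreedingModel} with at least one selected
#'   marker.
#' @param nReps number of independent breeding replicates.
#' @param seed integer RNG seed.
#' @return matrix with columns \code{left}, \code{right} (cM), one row per
#'   replicate.
#' @export
simulateFlankingCM <- function(model, nReps = 10000L, seed = 1L) {
  stopifnot(is(model, "BreedingModel"),
            length(model@selectedMarkers) >= 1L)
  validObject(model)
  set.seed(as.integer(seed))
  chr <- as.character(seqnames(model@selectedMarkers))[1L]
  lenCM <- model@geneticLengths[[chr]]
  mk <- model@selectedMarkers
  mkCM <- start(mk[seqnames(mk) == chr]) / model@bpPerCM
  at <- mkCM[1L]
  out <- matrix(NA_real_, nReps, 2L,
                dimnames = list(NULL, c("left", "right")))
  for (r in seq_len(nReps)) {
    hap <- list(breaks = c(0, lenCM), origin = "donor")
    for (g in seq_len(model@nBackcrosses))
      hap <- transmitGamete(hap, lenCM, mkCM)
    i <- findInterval(at, hap$breaks, rightmost.closed = TRUE)
    out[r, ] <- c(at - hap$breaks[i], hap$breaks[i + 1L] - at)
  }
  out
}

#' One-sided donor flanking lengths around a selected marker
#'
#' Measures, in cM, how far the donor-origin segment containing the marker
#' extends to each side of it. The closed-form expectation after N
#' backcrosses is 100/N cM per side (see \code{\link{expectedFlanking}}).
#'
#' @param mosaic a \linkS4class{GenomeMosaic}.
#' @param chrom,pos marker location (bp).
#' @param bpPerCM base pairs per centimorgan.
#' @return named numeric \code{c(left, right)} in cM; \code{NA} if the
#'   marker does not sit on donor background.
#' @export
flankingLengths <- function(mosaic, chrom, pos, bpPerCM = 2e6) {
  seg <- mosaicSegments(mosaic)
  seg <- seg[seqnames(seg) == chrom]
  i <- which(start(seg) <= pos & end(seg) >= pos)
  if (length(i) != 1L || mcols(seg)$origin[i] != "donor")
    return(c(left = NA_real_, right = NA_real_))
  c(left = (pos - start(seg)[i] + 1) / bpPerCM,
    right = (end(seg)[i] - pos) / bpPerCM)
}

#' @rdname mosaicFromSegments
#' @param origin origin of the whole genome for \code{pureMosaic}.
#' @export
pureMosaic <- function(chromLengths, origin = c("donor", "recipient")) {
  origin <- match.arg(origin)
  if (origin == "recipient")
    return(mosaicFromSegments(chromLengths))
  mosaicFromSegments(chromLengths,
    data.frame(chrom = names(chromLengths), start = 0,
               end = unname(chromLengths)))
}
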