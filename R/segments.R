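## Binning of informative SNPs and delimitation of introgressed donor
## segments. Bin edges are 0-based half-open bp intervals [k*w, (k+1)*w);
## a position lying exactly on an edge belongs to the right-open bin that
## starts there.

#' Bin origin calls along a chromosome
#'
#' @param calls \code{GRanges} of origin calls (mcol \code{origin}) from
#'   \code{\link{classifyCongenicOrigin}}; uninformative sites are ignored.
#' @param binWidth bin width in bp (default 1 Mbp, the resolution used for
#'   the focal chromosome; 10 Mbp is typical genome-wide).
#' @param chromLengths optional named lengths; defaults to the calls'
#'   seqlengths, or the maximum observed position.
#' @return data.frame with columns \code{chrom}, \code{bin_start},
#'   \code{bin_end} (0-based half-open bp), \code{donor},
#'   \code{recipient}. Counts are conserved: their sum equals the number of
#'   informative input calls.
#' @export
binOriginCalls <- function(calls, binWidth = 1e6, chromLengths = NULL) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (is.null(chromLengths)) {
    sl <- seqlengths(calls)
    if (length(sl) && !any(is.na(sl))) chromLengths <- sl
  }
  chroms <- if (!is.null(chromLengths)) names(chromLengths) else
    unique(as.character(seqnames(calls)))
  out <- lapply(chroms, function(chr) {
    g <- calls[seqnames(calls) == chr]
    len <- if (!is.null(chromLengths)) chromLengths[[chr]] else
      max(c(start(g), binWidth))
    nBins <- as.integer(len %/% binWidth) + 1L
    idx <- as.integer(start(g) %/% binWidth)     # edge goes right
    org <- as.character(mcols(g)$origin)
    donor <- tabulate(idx[org == "donor_informative"] + 1L, nBins)
    recip <- tabulate(idx[org == "recipient_informative"] + 1L, nBins)
    data.frame(chrom = chr,
               bin_start = (seq_len(nBins) - 1) * binWidth,
               bin_end = seq_len(nBins) * binWidth,
               donor = donor, recipient = recip)
  })
  do.call(rbind, out)
}

#' Delimit introgressed donor segments from binned counts
#'
#' A bin is donor-labeled iff it holds at least \code{minSupport}
#' donor-informative SNPs and the donor fraction
#' donor/(donor+recipient) is at least \code{donorFraction}. Runs of donor
#' bins are merged across gaps of at most \code{maxGapBins} bins containing
#' no informative SNPs of either origin (expression deserts are tolerated
#' rather than treated as recipient evidence); segment boundaries are the
#' outer edges of the terminal donor bins.
#'
#' @param bins data.frame from \code{\link{binOriginCalls}}.
#' @param minSupport minimum donor-informative SNPs per donor bin.
#' @param donorFraction minimum donor fraction per donor bin.
#' @param maxGapBins maximum run of SNP-free bins bridged inside a segment.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open bp), \code{n_donor_snps}, \code{n_recipient_snps}.
#' @export
detectSegments <- function(bins, minSupport = 3, donorFraction = 0.8,
                           maxGapBins = 2) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_donor_snps = integer(0),
                      n_recipient_snps = integer(0))
  if (is.null(bins) || nrow(bins) == 0L) return(empty)
  out <- empty
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    tot <- b$donor + b$recipient
    isDonor <- b$donor >= minSupport &
      ifelse(tot > 0, b$donor / tot, 0) >= donorFraction
    isEmpty <- tot == 0
    donorIdx <- which(isDonor)
    if (length(donorIdx) == 0L) next
    segStart <- donorIdx[1L]; prev <- donorIdx[1L]
    runs <- list()
    for (i in donorIdx[-1L]) {
      gap <- (prev + 1L):(i - 1L)
      bridge <- i - prev - 1L <= maxGapBins &&
        (i - prev <= 1L || all(isEmpty[gap]))
      if (!bridge) {
        runs[[length(runs) + 1L]] <- c(segStart, prev)
        segStart <- i
      }
      prev <- i
    }
    runs[[length(runs) + 1L]] <- c(segStart, prev)
    for (rn in runs) {
      sel <- rn[1L]:rn[2L]
      out <- rbind(out, data.frame(
        chrom = chr, start = b$bin_start[rn[1L]], end = b$bin_end[rn[2L]],
        n_donor_snps = as.integer(sum(b$donor[sel])),
        n_recipient_snps = as.integer(sum(b$recipient[sel]))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Cumulative genomic length of a set of segments, in Mbp
#'
#' @param segments data.frame with \code{chrom}, \code{start}, \code{end}
#'   (half-open bp); segments must not overlap.
#' @return total length in Mbp.
#' @export
#' @examples
#' cumulativeLength(data.frame(chrom = "chr1",
#'   start = c(100.6e6, 188.0e6), end = c(188.0e6, 250.4e6)))  # 149.8
cumulativeLength <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  if (any(segments$end <= segments$start))
    stop("segments must have end > start")
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping segments on ", chr)
  }
  sum(segments$end - segments$start) / 1e6
}

#' Expected residual donor flanking segment after N backcrosses
#'
#' Closed-form expectation for marker-assisted backcrossing: the donor
#' chromosomal segment flanking a selected marker is on average 100/N cM on
#' each side after N backcrosses, i.e. 2 * 100/N cM in total, converted to
#' bp at \code{bpPerCM} (1 cM is taken as 2e6 bp by default).
#'
#' @param model a \linkS4class{BreedingModel}, or the number of backcrosses
#'   N directly.
#' @param bpPerCM bp per cM, used when \code{model} is a plain number.
#' @return data.frame with \code{n_backcrosses}, \code{per_side_cM},
#'   \code{total_cM}, \code{per_side_bp}.
#' @export
#' @examples
#' expectedFlanking(8)   # 12.5 cM per side, 25 cM total
expectedFlanking <- function(model, bpPerCM = 2e6) {
  if (is(model, "BreedingModel")) {
    n <- model@nBackcrosses
    bpPerCM <- model@bpPerCM
  } else {
    n <- as.integer(model)
  }
  if (is.na(n) || n < 1L) stop("number of backcrosses must be >= 1")
  perSide <- 100 / n
  data.frame(n_backcrosses = n, per_side_cM = perSide,
             total_cM = 2 * perSide, per_side_bp = perSide * bpPerCM)
}

#' Genome-wide segment scan
#'
#' Bins and detects donor segments on every chromosome and reports the
#' chromosomes with no detected segment as clean. Chromosomes with zero
#' donor-informative calls never yield segments.
#'
#' @param calls origin calls (\code{GRanges}) across all chromosomes.
#' @param chromLengths named chromosome lengths (bp).
#' @param binWidth bin width (10 Mbp is typical for the genome-wide view).
#' @param ... passed to \code{\link{detectSegments}}.
#' @return list with \code{segments} (data.frame) and \code{clean}
#'   (character vector of segment-free chromosomes).
#' @export
genomeScan <- function(calls, chromLengths, binWidth = 1e7, ...) {
  bins <- binOriginCalls(calls, binWidth = binWidth,
                         chromLengths = chromLengths)
  segs <- detectSegments(bins, ...)
  clean <- setdiff(names(chromLengths), unique(segs$chrom))
  list(segments = segs, clean = clean)
}
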