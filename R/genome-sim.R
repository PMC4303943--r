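## Synthetic parental genomes: gene models plus a divergent-site table with
## per-strain truth alleles. Coding sequence is optional because only the
## consequence stage needs bases; segment mapping needs positions only.

BASES <- c("A", "C", "G", "T")

#' Simulate two divergent inbred parental genomes
#'
#' Places gene models (1-3 CDS exons each, total CDS a multiple of 3) along
#' each chromosome until roughly \code{codingFraction} of it is coding, then
#' scatters donor-vs-recipient divergent coding sites uniformly within CDS at
#' \code{snpDensity} expected sites per Mbp of chromosome. At each divergent
#' site one parent carries a non-reference allele; an additional
#' \code{sharedFraction * snpDensity} per Mbp of shared-alt sites carry the
#' same non-reference allele in both parents.
#'
#' @param spec a \linkS4class{GenomeSpec}.
#' @param genes optionally, a pre-built \linkS4class{GeneModelSet} to reuse
#'   (site placement is then redrawn under \code{spec@seed} without paying
#'   for gene-model construction again).
#' @param withSequence generate per-gene random coding sequences and make
#'   truth ref alleles consistent with them (needed for consequence
#'   annotation and FASTA output; off by default because it dominates run
#'   time on chromosome-scale genomes).
#' @return a list with elements \code{genes} (\linkS4class{GeneModelSet}),
#'   \code{sites} (a \code{GRanges} with mcols \code{ref}, \code{donor},
#'   \code{recipient}: the allele each parent carries), and
#'   \code{donorTruth} / \code{recipientTruth} (\code{GRanges} of the sites
#'   at which that parent differs from the reference, with \code{ref},
#'   \code{alt} mcols).
#' @export
#' @examples
#' spec <- genomeSpec(data.frame(name = "chr1", length = 5e6), seed = 7)
#' g <- simulateParentalGenomes(spec)
#' length(g$sites)
simulateParentalGenomes <- function(spec, genes = NULL,
                                    withSequence = FALSE) {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  set.seed(spec@seed)
  if (is.null(genes))
    genes <- simulateGeneModels(spec, withSequence = withSequence)
  chromLengths <- stats::setNames(spec@chromosomes$length,
                                  spec@chromosomes$name)
  sites <- placeDivergentSites(genes, chromLengths, spec)
  donorTruth <- sites[mcols(sites)$donor != mcols(sites)$ref]
  mcols(donorTruth) <- DataFrame(ref = mcols(donorTruth)$ref,
                                 alt = mcols(donorTruth)$donor)
  recipientTruth <- sites[mcols(sites)$recipient != mcols(sites)$ref]
  mcols(recipientTruth) <- DataFrame(ref = mcols(recipientTruth)$ref,
                                     alt = mcols(recipientTruth)$recipient)
  list(genes = genes, sites = sites, donorTruth = donorTruth,
       recipientTruth = recipientTruth)
}

## Gene structure parameters: CDS length 3 * U{100..500} (mean ~900 bp),
## 1-3 exons, introns U{100..2000} bp. Intergenic gaps are exponential with
## the mean solved so the expected coding fraction matches the requested value.
simulateGeneModels <- function(spec, withSequence = FALSE) {
  chroms <- spec@chromosomes
  gChromL <- list(); gStartL <- list(); gEndL <- list(); gStrandL <- list()
  exStartL <- list(); exEndL <- list(); exNL <- list()
  gid <- 0L
  for (i in seq_len(nrow(chroms))) {
    chr <- as.character(chroms$name[i]); len <- chroms$length[i]
    if (len <= 0) stop("zero-length chromosome: ", chr)
    meanCds <- 3 * mean(100:500)
    meanIntron <- mean(c(0, 1, 2)) * mean(100:2000)
    meanGap <- meanCds / spec@codingFraction - (meanCds + meanIntron)
    if (meanGap < 0)
      stop("codingFraction too high for the built-in gene geometry")
    nMax <- max(8L, ceiling(len / (meanCds + meanIntron + meanGap) * 1.4))
    cdsLen <- 3L * sample(100:500, nMax, replace = TRUE)
    nEx <- sample(1:3, nMax, replace = TRUE)
    in1 <- sample(100:2000, nMax, replace = TRUE)
    in2 <- sample(100:2000, nMax, replace = TRUE)
    intronTot <- ifelse(nEx == 1L, 0L,
                        ifelse(nEx == 2L, in1, in1 + in2))
    gaps <- stats::rexp(nMax, rate = 1 / max(meanGap, 1))
    foot <- cdsLen + intronTot
    ends <- cumsum(gaps + foot)
    starts <- as.integer(round(ends - foot)) + 1L
    ends <- starts + foot - 1L
    keep <- which(ends <= len)
    strands <- sample(c("+", "-"), length(keep), replace = TRUE)
    chrExStart <- vector("list", length(keep))
    chrExEnd <- vector("list", length(keep))
    for (kk in seq_along(keep)) {
      k <- keep[kk]
      ne <- nEx[k]
      exw <- if (ne == 1L) cdsLen[k] else {
        cuts <- sort(sample.int(cdsLen[k] - 1L, ne - 1L))
        diff(c(0L, cuts, cdsLen[k]))
      }
      inw <- if (ne == 1L) integer(0) else if (ne == 2L) in1[k] else
        c(in1[k], in2[k])
      es <- starts[k] + cumsum(c(0L, (exw + c(inw, 0L))[-ne]))
      ee <- es + exw - 1L
      ord <- if (strands[kk] == "-") rev(seq_len(ne)) else seq_len(ne)
      chrExStart[[kk]] <- es[ord]
      chrExEnd[[kk]] <- ee[ord]
    }
    gid <- gid + length(keep)
    j <- length(gChromL) + 1L
    gChromL[[j]] <- rep(chr, length(keep))
    gStartL[[j]] <- starts[keep]; gEndL[[j]] <- ends[keep]
    gStrandL[[j]] <- strands
    exStartL[[j]] <- unlist(chrExStart, use.names = FALSE)
    exEndL[[j]] <- unlist(chrExEnd, use.names = FALSE)
    exNL[[j]] <- nEx[keep]
  }
  if (gid == 0L)
    stop("no gene fits on the given chromosomes; enlarge them")
  ids <- sprintf("gene%05d", seq_len(gid))
  gChrom <- unlist(gChromL); gStart <- unlist(gStartL)
  gEnd <- unlist(gEndL); gStrand <- unlist(gStrandL)
  exN <- unlist(exNL)
  genes <- GRanges(gChrom, IRanges(gStart, gEnd), strand = gStrand)
  mcols(genes) <- DataFrame(gene_id = ids, symbol = toupper(ids))
  sl <- stats::setNames(chroms$length, chroms$name)
  seqlevels(genes) <- names(sl); seqlengths(genes) <- sl
  exGene <- rep(seq_len(gid), exN)
  flat <- GRanges(gChrom[exGene], IRanges(unlist(exStartL),
                                          unlist(exEndL)),
                  strand = gStrand[exGene])
  cds <- GenomicRanges::split(flat, factor(ids[exGene], levels = ids))
  totals <- sum(width(cds))
  fill <- if (withSequence) {
    function(w) paste(sample(BASES, w, replace = TRUE), collapse = "")
  } else {
    function(w) strrep("N", w)
  }
  seqs <- DNAStringSet(vapply(as.integer(totals), fill, character(1)))
  names(seqs) <- names(cds)
  new("GeneModelSet", genes = genes, cds = cds, codingSeq = seqs)
}

placeDivergentSites <- function(genes, chromLengths, spec) {
  cdsAll <- unlist(cdsRanges(genes), use.names = FALSE)
  empty <- GRanges(seqinfo = Seqinfo(names(chromLengths),
                                     unname(chromLengths)))
  mcols(empty) <- DataFrame(ref = character(0), donor = character(0),
                            recipient = character(0))
  if (spec@snpDensity <= 0) return(empty)
  totMbp <- sum(chromLengths) / 1e6
  nDiv <- stats::rpois(1L, spec@snpDensity * totMbp)
  nShared <- stats::rpois(1L, spec@sharedFraction * spec@snpDensity * totMbp)
  n <- nDiv + nShared
  if (n == 0L) return(empty)
  pos <- sampleCdsPositions(cdsAll, n)
  dup <- duplicated(paste(pos$chrom, pos$pos))
  pos <- pos[!dup, , drop = FALSE]
  nDiv <- min(nDiv, nrow(pos))
  n <- nrow(pos)
  gr <- GRanges(pos$chrom, IRanges(pos$pos, width = 1L),
                seqinfo = Seqinfo(names(chromLengths),
                                  unname(chromLengths)))
  ref <- refBaseAt(genes, gr)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  donorHasAlt <- stats::runif(n) < spec@donorAltFraction
  shared <- rep(FALSE, n)
  if (n > nDiv) shared[(nDiv + 1L):n] <- TRUE
  donor <- ifelse(shared | donorHasAlt, alt, ref)
  recipient <- ifelse(shared | !donorHasAlt, alt, ref)
  mcols(gr) <- DataFrame(ref = unname(ref), donor = unname(donor),
                         recipient = unname(recipient))
  o <- order(as.factor(seqnames(gr)), start(gr))
  gr[o]
}

## Uniform positions within CDS intervals: pick an interval with probability
## proportional to width, then a uniform offset inside it.
sampleCdsPositions <- function(cdsAll, n) {
  w <- width(cdsAll)
  idx <- sample.int(length(cdsAll), n, replace = TRUE, prob = w)
  off <- floor(stats::runif(n) * w[idx])
  data.frame(chrom = as.character(seqnames(cdsAll))[idx],
             pos = start(cdsAll)[idx] + off)
}

## Reference (genomic forward strand) base at each site. Sites always fall in
## CDS; when sequences were not generated ('N') a random base is assigned.
refBaseAt <- function(genes, gr) {
  noSeq <- length(genes) > 0L &&
    as.character(subseq(codingSeqs(genes)[[1L]], 1L, 1L)) == "N"
  if (noSeq)
    return(sample(BASES, length(gr), replace = TRUE))
  hits <- findOverlaps(gr, cdsRanges(genes))
  base <- rep(NA_character_, length(gr))
  qh <- queryHits(hits)
  first <- !duplicated(qh)
  for (k in which(first)) {
    i <- qh[k]
    gidx <- subjectHits(hits)[k]
    cp <- genomicToCds(cdsRanges(genes)[[gidx]], start(gr)[i])
    b <- as.character(subseq(codingSeqs(genes)[[gidx]], cp, cp))
    if (b == "N") b <- sample(BASES, 1L)
    else if (as.character(strand(cdsRanges(genes)[[gidx]])[1L]) == "-")
      b <- as.character(reverseComplement(DNAString(b)))
    base[i] <- b
  }
  miss <- is.na(base)
  if (any(miss)) base[miss] <- sample(BASES, sum(miss), replace = TRUE)
  base
}
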