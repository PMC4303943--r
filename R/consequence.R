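## Coding-consequence annotation: genomic SNP -> CDS coordinate -> codon ->
## amino-acid change, with SIFT-score classification. Standard nuclear
## genetic code only.

#' Map a genomic position to its 1-based CDS coordinate
#'
#' @param cds \code{GRanges} of CDS intervals in transcript orientation
#'   (minus-strand genes: descending genomic order).
#' @param pos genomic position (1-based).
#' @return integer CDS offset, or NA when the position is outside the CDS.
#' @export
genomicToCds <- function(cds, pos) {
  minus <- as.character(strand(cds))[1L] == "-"
  offs <- cumsum(c(0L, width(cds)))
  for (j in seq_along(cds)) {
    if (pos >= start(cds)[j] && pos <= end(cds)[j]) {
      within <- if (minus) end(cds)[j] - pos + 1L else
        pos - start(cds)[j] + 1L
      return(offs[j] + within)
    }
  }
  NA_integer_
}

#' Annotate the coding consequence of a SNP within a gene model
#'
#' Maps the genomic position to its CDS coordinate (strand-aware; alleles
#' of minus-strand genes are complemented into coding orientation),
#' substitutes the alternate base into the affected codon, translates both
#' codons with the standard genetic code and classifies the change as
#' synonymous, missense or nonsense. The codon-change string capitalizes
#' exactly the substituted base, at slot \code{((cds_position-1) mod 3)+1}.
#'
#' @param gms a \linkS4class{GeneModelSet}.
#' @param geneId gene to annotate against.
#' @param chrom,pos,ref,alt the SNP (genomic forward-strand alleles).
#' @param siftScore optional SIFT score in [0, 1], classified with
#'   \code{\link{siftClassify}}.
#' @return one-row data.frame: \code{gene_id}, \code{symbol},
#'   \code{allele} (genomic alternate base, as variant tables report it),
#'   \code{strand}, \code{cds_position}, \code{protein_position},
#'   \code{ref_aa}, \code{alt_aa}, \code{aa_change}, \code{codon_change},
#'   \code{consequence_class}, \code{sift_score}, \code{sift_class}.
#' @export
annotateConsequence <- function(gms, geneId, chrom, pos, ref, alt,
                                siftScore = NA_real_) {
  stopifnot(is(gms, "GeneModelSet"))
  i <- match(geneId, mcols(gms@genes)$gene_id)
  if (is.na(i)) stop("unknown gene: ", geneId)
  cds <- gms@cds[[geneId]]
  if (as.character(seqnames(cds))[1L] != chrom)
    stop("SNP chromosome ", chrom, " does not match gene ", geneId)
  cdsPos <- genomicToCds(cds, pos)
  if (is.na(cdsPos))
    stop("position ", pos, " lies outside the CDS of ", geneId)
  cdsPos <- as.integer(cdsPos)
  minus <- as.character(strand(cds))[1L] == "-"
  codingRef <- if (minus) complementBase(ref) else toupper(ref)
  codingAlt <- if (minus) complementBase(alt) else toupper(alt)
  seq <- gms@codingSeq[[geneId]]
  seqRef <- as.character(subseq(seq, cdsPos, cdsPos))
  if (seqRef != codingRef)
    stop("reference mismatch at CDS position ", cdsPos, " of ", geneId,
         ": VCF ref implies coding base '", codingRef,
         "' but the coding sequence has '", seqRef, "'")
  protPos <- as.integer(ceiling(cdsPos / 3))
  slot <- (cdsPos - 1L) %% 3L + 1L
  refCodon <- as.character(subseq(seq, 3L * protPos - 2L, 3L * protPos))
  altCodon <- refCodon
  substr(altCodon, slot, slot) <- codingAlt
  refAA <- GENETIC_CODE[[refCodon]]
  altAA <- GENETIC_CODE[[altCodon]]
  class <- if (refAA == altAA) "synonymous" else
    if (altAA == "*") "nonsense" else "missense"
  markCase <- function(codon) {
    x <- tolower(codon)
    substr(x, slot, slot) <- toupper(substr(codon, slot, slot))
    x
  }
  data.frame(gene_id = geneId, symbol = mcols(gms@genes)$symbol[i],
             allele = toupper(alt), strand = if (minus) "-" else "+",
             cds_position = cdsPos, protein_position = protPos,
             ref_aa = refAA, alt_aa = altAA,
             aa_change = paste(refAA, altAA, sep = "/"),
             codon_change = paste(markCase(refCodon), markCase(altCodon),
                                  sep = "/"),
             consequence_class = class, sift_score = siftScore,
             sift_class = siftClassify(siftScore),
             stringsAsFactors = FALSE)
}

#' Annotate every candidate SNP that falls in a CDS
#'
#' Vectorized wrapper over \code{\link{annotateConsequence}}: each SNP is
#' annotated against the gene whose CDS contains it; SNPs outside every CDS
#' are skipped.
#'
#' @param snps \code{GRanges} with mcols \code{ref}, \code{alt} (e.g. from
#'   \code{\link{candidateSnpFilter}}).
#' @param gms a \linkS4class{GeneModelSet}.
#' @param siftScores optional numeric vector aligned with \code{snps}.
#' @return data.frame of consequence records (possibly zero rows).
#' @export
annotateCandidates <- function(snps, gms, siftScores = NULL) {
  cdsAll <- gms@cds
  hits <- findOverlaps(granges(snps), cdsAll, ignore.strand = TRUE)
  qh <- queryHits(hits)
  first <- !duplicated(qh)
  rows <- lapply(which(first), function(k) {
    i <- qh[k]
    gid <- names(cdsAll)[subjectHits(hits)[k]]
    annotateConsequence(gms, gid, as.character(seqnames(snps))[i],
                        start(snps)[i], mcols(snps)$ref[i],
                        mcols(snps)$alt[i],
                        if (is.null(siftScores)) NA_real_ else
                          siftScores[i])
  })
  if (length(rows) == 0L)
    return(annotateEmpty())
  do.call(rbind, rows)
}

annotateEmpty <- function() {
  data.frame(gene_id = character(0), symbol = character(0),
             allele = character(0), strand = character(0),
             cds_position = integer(0), protein_position = integer(0),
             ref_aa = character(0), alt_aa = character(0),
             aa_change = character(0), codon_change = character(0),
             consequence_class = character(0), sift_score = numeric(0),
             sift_class = character(0), stringsAsFactors = FALSE)
}

#' Classify SIFT scores as deleterious or tolerated
#'
#' Scores from 0 to \code{deleteriousMax} (inclusive; the boundary score
#' 0.05 counts as deleterious) are deleterious, larger scores up to 1 are
#' tolerated, and missing scores are unscored.
#'
#' @param score numeric vector of SIFT scores in [0, 1]; NA allowed.
#' @param deleteriousMax deleterious/tolerated boundary (default 0.05).
#' @return character vector: \code{"deleterious"}, \code{"tolerated"} or
#'   \code{"unscored"}.
#' @export
#' @examples
#' siftClassify(c(0, 0.05, 0.46, NA))
siftClassify <- function(score, deleteriousMax = 0.05) {
  stopifnot(deleteriousMax > 0, deleteriousMax < 1)
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("SIFT scores must lie in [0, 1]")
  ifelse(is.na(score), "unscored",
         ifelse(score <= deleteriousMax, "deleterious", "tolerated"))
}
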