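#' Packaged candidate non-synonymous SNP table
#'
#' The published table of genes inside the two congenic loci that carry
#' non-synonymous coding SNPs (present in the donor and the congenic carrier
#' but absent in the recipient), with VEP-style annotation columns: variant
#' allele, CDS position, protein position, amino-acid change, codon change
#' with the substituted base capitalized, and the SIFT prediction with its
#' score. Shipped as a machine-readable golden input for the consequence
#' annotator and the candidate-nomination stage.
#'
#' @return data.frame with one row per SNP (22 rows across 19 genes).
#'   \code{sift_score} is \code{NA} where the table reports no score.
#' @export
#' @examples
#' t1 <- publishedCandidateSnps()
#' table(t1$locus)
publishedCandidateSnps <- function() {
  path <- system.file("extdata", "published_candidate_snps.tsv",
                      package = "introscan", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$cds_position <- as.integer(df$cds_position)
  df$protein_position <- as.integer(df$protein_position)
  df$sift_score <- suppressWarnings(as.numeric(df$sift_score))
  df$sift_prediction[df$sift_prediction == "-"] <- NA_character_
  df$colocated_variation[df$colocated_variation == "-"] <- NA_character_
  df
}

#' Build toy gene models embedding the packaged candidate-SNP table
#'
#' For each fixture row, constructs a single-exon gene whose coding sequence
#' carries the row's reference codon at the stated CDS position (all other
#' codons are a neutral filler), plus the corresponding genomic SNP. Strand
#' is inferred from the reported variant allele: when it equals the
#' coding-strand alternate base the gene is placed on the plus strand,
#' when it equals its complement, on the minus strand. This reconstructs a
#' miniature genome on which the consequence annotator must reproduce every
#' row of the table.
#'
#' @param rows optional subset of \code{\link{publishedCandidateSnps}()}.
#' @return list with \code{genes} (a \linkS4class{GeneModelSet}),
#'   \code{snps} (data.frame chrom, pos, ref, alt, gene_id) and
#'   \code{table} (the fixture rows used).
#' @export
candidateToyGenome <- function(rows = publishedCandidateSnps()) {
  fillerCodon <- "GCT"   # alanine; never a stop
  geneList <- list(); cdsList <- list(); seqList <- character()
  snps <- NULL
  offset <- 0L
  ids <- sprintf("cand%02d", seq_len(nrow(rows)))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    codons <- strsplit(r$codon_change, "/", fixed = TRUE)[[1L]]
    refCodon <- toupper(codons[1L]); altCodon <- toupper(codons[2L])
    slot <- which(strsplit(codons[1L], "")[[1L]] %in% LETTERS)
    stopifnot(length(slot) == 1L)
    protPos <- ceiling(r$cds_position / 3)
    nCodons <- protPos + 1L
    seqChars <- rep(fillerCodon, nCodons)
    seqChars[protPos] <- refCodon
    codingSeq <- paste(seqChars, collapse = "")
    cdsLen <- 3L * nCodons
    refCoding <- substr(refCodon, slot, slot)
    altCoding <- substr(altCodon, slot, slot)
    strand <- if (identical(r$allele, altCoding)) "+" else "-"
    start <- offset + 1L
    end <- offset + cdsLen
    cds <- GRanges("toychr", IRanges(start, end), strand = strand)
    gr <- cds
    mcols(gr) <- DataFrame(gene_id = ids[i], symbol = r$gene_symbol)
    geneList[[ids[i]]] <- gr
    cdsList[[ids[i]]] <- cds
    seqList[ids[i]] <- codingSeq
    # genomic coordinates of the changed base
    if (strand == "+") {
      pos <- start + r$cds_position - 1L
      ref <- refCoding; alt <- altCoding
    } else {
      pos <- end - r$cds_position + 1L
      ref <- complementBase(refCoding); alt <- complementBase(altCoding)
    }
    snps <- rbind(snps, data.frame(chrom = "toychr", pos = pos, ref = ref,
                                   alt = alt, gene_id = ids[i]))
    offset <- end + 100L
  }
  genes <- do.call(c, unname(geneList))
  chromLen <- offset + 100L
  seqlevels(genes) <- "toychr"
  seqlengths(genes) <- c(toychr = chromLen)
  gms <- new("GeneModelSet", genes = genes,
             cds = GRangesList(cdsList),
             codingSeq = DNAStringSet(seqList))
  list(genes = gms, snps = snps, table = rows)
}

complementBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]
}
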