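suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
})

## QUAL-filter an observation into a StrainVariants, as the VCF reader would
qualFilter <- function(o, minQual = 100) {
  g <- variantCalls(o)
  g <- g[mcols(g)$qual >= minQual]
  new("StrainVariants", calls = g, strain = strain(o))
}

## random biallelic variant table on one chromosome
randomStrainTable <- function(n, strainLabel, chromLen = 1e6, seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(chromLen, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  strainVariants("chr1", pos, ref, alt, qual = runif(n, 100, 300),
                 strain = strainLabel, seqlengths = c(chr1 = chromLen))
}

## hand-built two-gene model set: one single-exon plus gene, one two-exon
## minus gene, on a 600-bp chromosome whose sequence is returned alongside
tinyGeneModelSet <- function() {
  set.seed(99)
  chromSeq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                    collapse = "")
  plusCds <- GRanges("chrT", IRanges(101, 130), strand = "+")
  plusSeq <- substr(chromSeq, 101, 130)
  minusCds <- GRanges("chrT", IRanges(c(451, 401), c(480, 421)),
                      strand = "-")   # transcript orientation: high first
  spliced <- paste0(substr(chromSeq, 401, 421),
                    substr(chromSeq, 451, 480))
  minusSeq <- as.character(
    reverseComplement(DNAString(spliced)))
  genes <- GRanges("chrT", IRanges(c(101, 401), c(130, 480)),
                   strand = c("+", "-"))
  mcols(genes) <- DataFrame(gene_id = c("gplus", "gminus"),
                            symbol = c("GPLUS", "GMINUS"))
  seqlevels(genes) <- "chrT"
  seqlengths(genes) <- c(chrT = 600)
  gms <- new("GeneModelSet", genes = genes,
             cds = GRangesList(gplus = plusCds, gminus = minusCds),
             codingSeq = DNAStringSet(c(gplus = plusSeq,
                                        gminus = minusSeq)))
  list(gms = gms, chromSeq = chromSeq)
}

## independent full-translation oracle: translate the complete coding
## sequence before and after substituting the alt base at cdsPos
translationOracle <- function(codingSeq, cdsPos, altCodingBase) {
  before <- as.character(translate(DNAString(codingSeq),
                                   if.fuzzy.codon = "X"))
  mutated <- codingSeq
  substr(mutated, cdsPos, cdsPos) <- altCodingBase
  after <- as.character(translate(DNAString(mutated),
                                  if.fuzzy.codon = "X"))
  list(before = before, after = after,
       changedAt = which(strsplit(before, "")[[1]] !=
                           strsplit(after, "")[[1]]))
}
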