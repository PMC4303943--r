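test_that("CDS coordinates map to protein positions and codon slots", {
  # plus-strand gene carrying AGA at CDS 667-669; A->G at the first slot
  nCodons <- 225
  seqChars <- rep("GCT", nCodons)
  seqChars[223] <- "AGA"
  gms <- new("GeneModelSet",
    genes = GRanges("chr1", IRanges(1, nCodons * 3),
                    strand = "+",
                    gene_id = "hps5", symbol = "Hps5"),
    cds = GRangesList(hps5 = GRanges("chr1", IRanges(1, nCodons * 3),
                                     strand = "+")),
    codingSeq = DNAStringSet(c(hps5 = paste(seqChars, collapse = ""))))
  rec <- annotateConsequence(gms, "hps5", "chr1", 667, "A", "G")
  expect_identical(rec$cds_position, 667L)
  expect_identical(rec$protein_position, 223L)
  expect_identical(rec$aa_change, "R/G")
  expect_identical(rec$codon_change, "Aga/Gga")
  expect_identical(rec$consequence_class, "missense")
  # third base of the first codon: protein position 1, slot 3
  rec3 <- annotateConsequence(gms, "hps5", "chr1", 3, "T", "A")
  expect_identical(rec3$protein_position, 1L)
  expect_identical(rec3$codon_change, "gcT/gcA")
})

test_that("the Cebpg row exercises slot 2 on the minus strand", {
  # aGc -> aAc at CDS 410 (protein 137): embed on a minus-strand gene so
  # the genomic alleles are the complements C->T
  nCodons <- 138
  seqChars <- rep("GCT", nCodons)
  seqChars[137] <- "AGC"
  codingSeq <- paste(seqChars, collapse = "")
  len <- nCodons * 3
  gms <- new("GeneModelSet",
    genes = GRanges("chr1", IRanges(1001, 1000 + len), strand = "-",
                    gene_id = "cebpg", symbol = "Cebpg"),
    cds = GRangesList(cebpg = GRanges("chr1",
                                      IRanges(1001, 1000 + len),
                                      strand = "-")),
    codingSeq = DNAStringSet(c(cebpg = codingSeq)))
  pos <- 1000 + len - 410 + 1       # genomic position of CDS offset 410
  rec <- annotateConsequence(gms, "cebpg", "chr1", pos, "C", "T")
  expect_identical(rec$cds_position, 410L)
  expect_identical(rec$protein_position, 137L)
  expect_identical(rec$aa_change, "S/N")
  expect_identical(rec$codon_change, "aGc/aAc")
  expect_identical(rec$strand, "-")
})

test_that("random SNPs agree with the full-translation oracle", {
  set.seed(121)
  nCodons <- 80
  codingSeq <- paste(sample(c("GCT", "AAA", "TGG", "CTT", "AGA", "TCA",
                              "GGG", "TAT"), nCodons, TRUE),
                     collapse = "")
  len <- nCodons * 3
  for (strand in c("+", "-")) {
    start <- 501
    gms <- new("GeneModelSet",
      genes = GRanges("chrZ", IRanges(start, start + len - 1),
                      strand = strand, gene_id = "g", symbol = "G"),
      cds = GRangesList(g = GRanges("chrZ",
                                    IRanges(start, start + len - 1),
                                    strand = strand)),
      codingSeq = DNAStringSet(c(g = codingSeq)))
    for (i in 1:500) {
      cdsPos <- sample.int(len, 1)
      refCoding <- substr(codingSeq, cdsPos, cdsPos)
      altCoding <- sample(setdiff(c("A", "C", "G", "T"), refCoding), 1)
      if (strand == "+") {
        pos <- start + cdsPos - 1
        ref <- refCoding; alt <- altCoding
      } else {
        pos <- start + len - cdsPos
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ref <- comp[[refCoding]]; alt <- comp[[altCoding]]
      }
      rec <- annotateConsequence(gms, "g", "chrZ", pos, ref, alt)
      oracle <- translationOracle(codingSeq, cdsPos, altCoding)
      expect_identical(rec$cds_position, as.integer(cdsPos))
      expect_identical(rec$protein_position,
                       as.integer(ceiling(cdsPos / 3)))
      if (rec$consequence_class == "synonymous") {
        expect_length(oracle$changedAt, 0)
      } else {
        expect_identical(oracle$changedAt,
                         as.integer(rec$protein_position))
        expect_identical(
          substr(oracle$after, rec$protein_position,
                 rec$protein_position), rec$alt_aa)
      }
    }
  }
})

test_that("a gene and its reverse-complement mirror annotate identically", {
  set.seed(131)
  nCodons <- 40
  codingSeq <- paste(sample(c("GCT", "AGA", "TGC", "CTT"), nCodons, TRUE),
                     collapse = "")
  len <- nCodons * 3
  plus <- new("GeneModelSet",
    genes = GRanges("chrM", IRanges(101, 100 + len), strand = "+",
                    gene_id = "g", symbol = "G"),
    cds = GRangesList(g = GRanges("chrM", IRanges(101, 100 + len),
                                  strand = "+")),
    codingSeq = DNAStringSet(c(g = codingSeq)))
  minus <- new("GeneModelSet",
    genes = GRanges("chrM", IRanges(101, 100 + len), strand = "-",
                    gene_id = "g", symbol = "G"),
    cds = GRangesList(g = GRanges("chrM", IRanges(101, 100 + len),
                                  strand = "-")),
    codingSeq = DNAStringSet(c(g = codingSeq)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:50) {
    cdsPos <- sample.int(len, 1)
    refCoding <- substr(codingSeq, cdsPos, cdsPos)
    altCoding <- sample(setdiff(c("A", "C", "G", "T"), refCoding), 1)
    recP <- annotateConsequence(plus, "g", "chrM", 100 + cdsPos,
                                refCoding, altCoding)
    recM <- annotateConsequence(minus, "g", "chrM", 100 + len - cdsPos + 1,
                                comp[[refCoding]], comp[[altCoding]])
    expect_identical(recP$cds_position, recM$cds_position)
    expect_identical(recP$aa_change, recM$aa_change)
    expect_identical(recP$codon_change, recM$codon_change)
    expect_identical(recP$consequence_class, recM$consequence_class)
  }
})

test_that("stop gains are labelled nonsense and excluded from missense", {
  gms <- new("GeneModelSet",
    genes = GRanges("chr1", IRanges(1, 9), strand = "+",
                    gene_id = "g", symbol = "G"),
    cds = GRangesList(g = GRanges("chr1", IRanges(1, 9), strand = "+")),
    codingSeq = DNAStringSet(c(g = "ATGTGTGCT")))
  rec <- annotateConsequence(gms, "g", "chr1", 6, "T", "A")  # TGT -> TGA
  expect_identical(rec$consequence_class, "nonsense")
  expect_identical(rec$alt_aa, "*")
})

test_that("out-of-CDS positions and reference mismatches are errors", {
  fx <- tinyGeneModelSet()
  expect_error(annotateConsequence(fx$gms, "gplus", "chrT", 50, "A", "G"),
               "outside the CDS")
  refBase <- substr(fx$chromSeq, 101, 101)
  wrong <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(refBase, wrong))[1]
  expect_error(annotateConsequence(fx$gms, "gplus", "chrT", 101, wrong,
                                   alt),
               "reference mismatch")
})

test_that("SIFT classification uses the inclusive 0-0.05 deleterious rule", {
  expect_identical(siftClassify(0), "deleterious")
  expect_identical(siftClassify(0.05), "deleterious")  # boundary inclusive
  expect_identical(siftClassify(0.051), "tolerated")
  expect_identical(siftClassify(0.46), "tolerated")
  expect_identical(siftClassify(1), "tolerated")
  expect_identical(siftClassify(NA_real_), "unscored")
  expect_identical(siftClassify(c(0, 0.46, NA)),
                   c("deleterious", "tolerated", "unscored"))
  expect_error(siftClassify(1.2), "0, 1")
})

test_that("every published candidate row reproduces on its toy gene", {
  t1 <- publishedCandidateSnps()
  toy <- candidateToyGenome()
  for (i in seq_len(nrow(t1))) {
    s <- toy$snps[i, ]
    rec <- annotateConsequence(toy$genes, s$gene_id, s$chrom, s$pos,
                               s$ref, s$alt,
                               siftScore = t1$sift_score[i])
    expect_identical(rec$cds_position, t1$cds_position[i])
    expect_identical(rec$protein_position, t1$protein_position[i])
    expect_identical(rec$aa_change, t1$aa_change[i])
    expect_identical(rec$codon_change, t1$codon_change[i])
    expect_identical(rec$allele, t1$allele[i])
    expect_identical(rec$consequence_class, "missense")
  }
})
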