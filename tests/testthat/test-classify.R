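test_that("strain-specific partitioning follows the allele definitions", {
  donor <- strainVariants("chr1", c(100, 200, 300), ref = c("A", "C", "G"),
                          alt = c("G", "T", "A"), qual = 200,
                          strain = "donor")
  recip <- strainVariants("chr1", c(200, 400), ref = c("C", "T"),
                          alt = c("T", "C"), qual = 200,
                          strain = "recipient")
  sp <- strainSpecificSites(donor, recip)
  expect_setequal(start(sp$donorSpecific), c(100, 300))  # donor-only alts
  expect_identical(start(sp$recipientSpecific), 400L)
  expect_identical(start(sp$shared), 200L)               # alt in both
})

test_that("conflicting reference alleles discard the site with a warning", {
  donor <- strainVariants("chr1", c(100, 200), ref = c("A", "C"),
                          alt = c("G", "T"), qual = 200, strain = "donor")
  recip <- strainVariants("chr1", c(100, 300), ref = c("T", "G"),
                          alt = c("C", "A"), qual = 200,
                          strain = "recipient")
  expect_warning(sp <- strainSpecificSites(donor, recip), "reference")
  expect_identical(start(sp$donorSpecific), 200L)
  expect_identical(start(sp$recipientSpecific), 300L)
})

test_that("random partitions equal brute-force three-way set algebra", {
  for (s in 1:3) {
    donor <- randomStrainTable(200, "donor", seed = 100 + s)
    recip <- randomStrainTable(200, "recipient", seed = 200 + s)
    sp <- strainSpecificSites(donor, recip)
    # brute force over every site key
    d <- variantCalls(donor); r <- variantCalls(recip)
    dKey <- paste(start(d), mcols(d)$alt)
    rKey <- paste(start(r), mcols(r)$alt)
    refConf <- intersect(start(d)[!(dKey %in% rKey)],
                         start(r)[!(rKey %in% dKey)])
    refConf <- refConf[
      mcols(d)$ref[match(refConf, start(d))] !=
        mcols(r)$ref[match(refConf, start(r))]]
    dSpec <- setdiff(start(d)[!(dKey %in% rKey)], refConf)
    rSpec <- setdiff(start(r)[!(rKey %in% dKey)], refConf)
    shared <- start(d)[dKey %in% rKey]
    sp <- suppressWarnings(strainSpecificSites(donor, recip))
    expect_setequal(start(sp$donorSpecific), dSpec)
    expect_setequal(start(sp$recipientSpecific), rSpec)
    expect_setequal(start(sp$shared), shared)
  }
})

test_that("swapping donor and recipient swaps the specific sets exactly", {
  donor <- randomStrainTable(150, "donor", seed = 11)
  recip <- randomStrainTable(150, "recipient", seed = 12)
  a <- suppressWarnings(strainSpecificSites(donor, recip))
  b <- suppressWarnings(strainSpecificSites(recip, donor))
  expect_identical(start(a$donorSpecific), start(b$recipientSpecific))
  expect_identical(start(a$recipientSpecific), start(b$donorSpecific))
})

test_that("congenic origin labels follow the evidence rules", {
  dSpec <- GRanges("chr1", IRanges(c(100, 200, 300), width = 1))
  mcols(dSpec) <- DataFrame(ref = c("A", "C", "G"),
                            alt = c("G", "T", "A"))
  rSpec <- GRanges("chr1", IRanges(400, width = 1))
  mcols(rSpec) <- DataFrame(ref = "T", alt = "C")
  congenic <- strainVariants("chr1", 100, ref = "A", alt = "G",
                             qual = 200, strain = "congenic")
  covered <- GRanges("chr1", IRanges(c(100, 200), width = 1))
  calls <- classifyCongenicOrigin(congenic, dSpec, rSpec, covered)
  org <- setNames(as.character(mcols(calls)$origin), start(calls))
  expect_identical(org[["100"]], "donor_informative")    # matching alt
  expect_identical(org[["200"]], "recipient_informative") # absent, covered
  expect_identical(org[["300"]], "uninformative")  # absent, no coverage
  expect_identical(org[["400"]], "uninformative")
  # partition completeness: every input site gets exactly one label
  expect_identical(sort(start(calls)), c(100L, 200L, 300L, 400L))
  # symmetric logic: swap the roles of the site classes
  swapped <- classifyCongenicOrigin(congenic, rSpec, dSpec, covered)
  sorg <- setNames(as.character(mcols(swapped)$origin), start(swapped))
  expect_identical(sorg[["100"]], "recipient_informative")
  expect_identical(sorg[["400"]], "uninformative")
})

test_that("error-free synthetic data classifies at 100% accuracy", {
  spec <- genomeSpec(data.frame(name = "chr1", length = 2e7), seed = 77)
  sim <- simulateParentalGenomes(spec)
  chromLengths <- c(chr1 = 2e7)
  mosaic <- mosaicFromSegments(chromLengths,
                               data.frame(chrom = "chr1", start = 5e6,
                                          end = 1.2e7))
  clean <- observationModel(coverageDropout = 0, errorRate = 0)
  donorTab <- qualFilter(observeVariants(
    pureMosaic(chromLengths, "donor"), sim$sites, clean, "donor", 1))
  recipTab <- qualFilter(observeVariants(
    pureMosaic(chromLengths, "recipient"), sim$sites, clean,
    "recipient", 2))
  congObs <- observeVariants(mosaic, sim$sites, clean, "congenic", 3)
  sp <- strainSpecificSites(donorTab, recipTab)
  calls <- classifyCongenicOrigin(qualFilter(congObs), sp$donorSpecific,
                                  sp$recipientSpecific,
                                  coveredSites(congObs))
  inf <- calls[mcols(calls)$origin != "uninformative"]
  expect_gt(length(inf), 100)
  truthOrigin <- originAtPositions(mosaic, inf)
  called <- ifelse(mcols(inf)$origin == "donor_informative", "donor",
                   "recipient")
  expect_identical(called, truthOrigin)
})

test_that("misclassification stays within twice the base-call error rate", {
  # parental tables enter as fully observed call sets; the congenic
  # observation carries the default dropout and error
  spec <- genomeSpec(data.frame(name = "chr1", length = 1e8), seed = 55)
  sim <- simulateParentalGenomes(spec)
  chromLengths <- c(chr1 = 1e8)
  mosaic <- mosaicFromSegments(chromLengths,
                               data.frame(chrom = "chr1", start = 2e7,
                                          end = 6e7))
  clean <- observationModel(coverageDropout = 0, errorRate = 0)
  noisy <- observationModel(coverageDropout = 0.2, errorRate = 0.005)
  donorTab <- qualFilter(observeVariants(
    pureMosaic(chromLengths, "donor"), sim$sites, clean, "donor", 1))
  recipTab <- qualFilter(observeVariants(
    pureMosaic(chromLengths, "recipient"), sim$sites, clean,
    "recipient", 2))
  congObs <- observeVariants(mosaic, sim$sites, noisy, "congenic", 3)
  sp <- strainSpecificSites(donorTab, recipTab)
  calls <- classifyCongenicOrigin(qualFilter(congObs), sp$donorSpecific,
                                  sp$recipientSpecific,
                                  coveredSites(congObs))
  inf <- calls[mcols(calls)$origin != "uninformative"]
  truthOrigin <- originAtPositions(mosaic, inf)
  called <- ifelse(mcols(inf)$origin == "donor_informative", "donor",
                   "recipient")
  expect_lte(mean(called != truthOrigin), 2 * 0.005)
})

test_that("candidate SNPs obey the donor+congenic-minus-recipient rule", {
  donor <- strainVariants("chr1", c(100, 200, 5000), ref = "A",
                          alt = "G", qual = 200, strain = "donor")
  recip <- strainVariants("chr1", 200, ref = "A", alt = "G", qual = 200,
                          strain = "recipient")
  congenic <- strainVariants("chr1", c(100, 200, 5000), ref = "A",
                             alt = "G", qual = 200, strain = "congenic")
  loci <- data.frame(chrom = "chr1", start = 0, end = 1000)
  cand <- candidateSnpFilter(donor, recip, congenic, loci)
  # 100: in locus, donor+congenic, not recipient -> kept
  # 200: recipient carries the alt -> excluded
  # 5000: outside the locus -> excluded
  expect_identical(start(cand), 100L)
  expect_warning(empty <- candidateSnpFilter(donor, recip, congenic,
                                             NULL),
                 "no congenic loci")
  expect_length(empty, 0)
})

test_that("candidate filtering equals a brute-force interval test", {
  set.seed(9)
  donor <- randomStrainTable(500, "donor", chromLen = 1e6, seed = 31)
  recip <- randomStrainTable(300, "recipient", chromLen = 1e6, seed = 32)
  congenic <- randomStrainTable(500, "congenic", chromLen = 1e6,
                                seed = 31)  # same table as donor
  loci <- data.frame(chrom = "chr1", start = c(1e5, 6e5),
                     end = c(3e5, 7e5))
  cand <- candidateSnpFilter(donor, recip, congenic, loci)
  d <- variantCalls(donor); r <- variantCalls(recip)
  cg <- variantCalls(congenic)
  keep <- vapply(seq_along(cg), function(i) {
    key <- paste(start(cg)[i], mcols(cg)$alt[i])
    inD <- key %in% paste(start(d), mcols(d)$alt)
    inR <- key %in% paste(start(r), mcols(r)$alt)
    inL <- any(start(cg)[i] > loci$start & start(cg)[i] <= loci$end)
    inD && !inR && inL
  }, logical(1))
  expect_identical(start(cand), start(cg)[keep])
})
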