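originCallsFixture <- function(pos, origin, chromLen = 1e7,
                               chrom = "chr1") {
  gr <- GRanges(rep(chrom, length(pos)), IRanges(pos, width = 1))
  mcols(gr)$origin <- factor(origin,
    levels = c("donor_informative", "recipient_informative",
               "uninformative"))
  seqlevels(gr) <- chrom
  seqlengths(gr) <- setNames(chromLen, chrom)
  gr
}

test_that("binning conserves counts and places edge positions rightward", {
  empty <- binOriginCalls(originCallsFixture(integer(0), character(0)),
                          1e6)
  expect_true(all(empty$donor == 0) && all(empty$recipient == 0))
  # position exactly on the 1 Mbp boundary belongs to [1e6, 2e6)
  b <- binOriginCalls(originCallsFixture(1e6, "donor_informative"), 1e6)
  hit <- b[b$donor > 0, ]
  expect_identical(hit$bin_start, 1e6)
  expect_identical(hit$bin_end, 2e6)
  expect_error(binOriginCalls(originCallsFixture(1, "donor_informative"),
                              0), "positive")
})

test_that("bin counts equal a brute-force tally on random calls", {
  set.seed(17)
  pos <- sample.int(1e7, 300)
  org <- sample(c("donor_informative", "recipient_informative",
                  "uninformative"), 300, replace = TRUE)
  bins <- binOriginCalls(originCallsFixture(pos, org), 1e6)
  expect_identical(sum(bins$donor), sum(org == "donor_informative"))
  expect_identical(sum(bins$recipient),
                   sum(org == "recipient_informative"))
  for (k in seq_len(nrow(bins))) {    # brute-force per bin
    inBin <- pos >= bins$bin_start[k] & pos < bins$bin_end[k]
    expect_identical(bins$donor[k],
                     sum(inBin & org == "donor_informative"))
    expect_identical(bins$recipient[k],
                     sum(inBin & org == "recipient_informative"))
  }
})

test_that("recipient-dominated chromosomes yield no segments", {
  pos <- seq(1e5, 9.9e6, by = 1e5)
  bins <- binOriginCalls(
    originCallsFixture(pos, rep("recipient_informative", length(pos))),
    1e6)
  expect_identical(nrow(detectSegments(bins)), 0L)
})

test_that("hand-built bin vectors merge across empty gaps only", {
  mk <- function(donor, recipient) {
    data.frame(chrom = "chr1", bin_start = (0:9) * 1e6,
               bin_end = (1:10) * 1e6, donor = donor,
               recipient = recipient)
  }
  # donor run with one SNP-free gap bin inside: single merged segment
  donor <- c(0, 5, 6, 0, 7, 5, 0, 0, 0, 0)
  segs <- detectSegments(mk(donor, rep(0, 10)))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start, 1e6)
  expect_identical(segs$end, 6e6)
  expect_identical(segs$n_donor_snps, 23L)
  # the same gap filled with recipient SNPs breaks the run
  recip <- c(0, 0, 0, 9, 0, 0, 0, 0, 0, 0)
  segs2 <- detectSegments(mk(donor, recip))
  expect_identical(nrow(segs2), 2L)
  expect_identical(segs2$end[1], 3e6)
  expect_identical(segs2$start[2], 4e6)
  # a gap longer than maxGapBins also breaks the run
  donor3 <- c(5, 5, 0, 0, 0, 5, 5, 0, 0, 0)
  expect_identical(nrow(detectSegments(mk(donor3, rep(0, 10)),
                                       maxGapBins = 2)), 2L)
  expect_identical(nrow(detectSegments(mk(donor3, rep(0, 10)),
                                       maxGapBins = 3)), 1L)
  # donor bins must meet both support and fraction thresholds
  segs4 <- detectSegments(mk(c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                             rep(0, 10)))
  expect_identical(nrow(segs4), 0L)
  segs5 <- detectSegments(mk(c(6, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                             c(3, 0, 0, 0, 0, 0, 0, 0, 0, 0)))
  expect_identical(nrow(segs5), 0L)   # fraction 6/9 < 0.8
})

test_that("detection is monotone in donor evidence", {
  set.seed(23)
  pos <- c(sample(2e6:4e6, 40), sample(6e6:8e6, 15))
  org <- rep("donor_informative", length(pos))
  calls <- originCallsFixture(pos, org)
  segs <- detectSegments(binOriginCalls(calls, 1e6))
  more <- originCallsFixture(c(pos, sample(2e6:4e6, 20)),
                             c(org, rep("donor_informative", 20)))
  segs2 <- detectSegments(binOriginCalls(more, 1e6))
  # every originally detected segment is still covered
  for (k in seq_len(nrow(segs))) {
    expect_true(any(segs2$start <= segs$start[k] &
                      segs2$end >= segs$end[k]))
  }
})

test_that("cumulative length sums half-open segments in Mbp", {
  qtl <- data.frame(chrom = "chr1", start = c(100.6e6, 188.0e6),
                    end = c(188.0e6, 250.4e6))
  expect_equal(cumulativeLength(qtl), 149.8)
  expect_equal(cumulativeLength(data.frame(chrom = "chr1", start = 0,
                                           end = 1e6)), 1.0)
  set.seed(3)   # 20 random disjoint segments vs brute-force sum
  starts <- sort(sample.int(1e8, 20)) + (0:19) * 2e6
  ends <- starts + sample.int(1e6, 20)
  segs <- data.frame(chrom = "chr1", start = starts, end = ends)
  expect_equal(cumulativeLength(segs), sum(ends - starts) / 1e6)
  expect_error(cumulativeLength(
    data.frame(chrom = "chr1", start = c(0, 5e5), end = c(1e6, 2e6))),
    "overlap")
})

test_that("the flanking expectation reproduces the backcross arithmetic", {
  fl <- expectedFlanking(8)
  expect_equal(fl$per_side_cM, 12.5)
  expect_equal(fl$total_cM, 25)
  expect_equal(fl$per_side_bp, 2.5e7)
  expect_equal(fl$per_side_cM * fl$n_backcrosses, 100)   # exact identity
  bm <- breedingModel(data.frame(name = "chr1", length = 2e8),
                      nBackcrosses = 5, bpPerCM = 1e6)
  fl5 <- expectedFlanking(bm)
  expect_equal(fl5$per_side_cM, 20)
  expect_equal(fl5$per_side_bp, 2e7)
})

test_that("the genome scan reports planted and clean chromosomes", {
  chromLengths <- c(chr1 = 1e8, chr2 = 8e7, chr3 = 6e7)
  set.seed(5)
  mkCalls <- function(chrom, donorRange, n = 60, nNoise = 40,
                      chromLen = 1e8) {
    pos <- c(sample(donorRange[1]:donorRange[2], n),
             sample.int(chromLen, nNoise))
    org <- c(rep("donor_informative", n),
             rep("recipient_informative", nNoise))
    GRanges(chrom, IRanges(pos, width = 1),
            origin = factor(org, levels = c("donor_informative",
              "recipient_informative", "uninformative")))
  }
  calls <- suppressWarnings(c(mkCalls("chr1", c(2e7, 5e7)),
                              mkCalls("chr2", c(1e7, 3e7),
                                      chromLen = 8e7)))
  noise3 <- GRanges("chr3", IRanges(sample.int(6e7, 30), width = 1),
                    origin = factor(rep("recipient_informative", 30),
                      levels = c("donor_informative",
                                 "recipient_informative",
                                 "uninformative")))
  scan <- genomeScan(suppressWarnings(c(calls, noise3)), chromLengths,
                     binWidth = 1e7)
  expect_setequal(unique(scan$segments$chrom), c("chr1", "chr2"))
  expect_identical(scan$clean, "chr3")
  # degenerate robustness: no donor-informative calls, no segments
  scanNull <- genomeScan(noise3, chromLengths, binWidth = 1e7)
  expect_identical(nrow(scanNull$segments), 0L)
  expect_setequal(scanNull$clean, names(chromLengths))
})
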