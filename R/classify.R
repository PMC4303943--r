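## Strain-of-origin classification of coding SNP sites by set comparison of
## donor, recipient and congenic variant tables.

siteKey <- function(gr) paste(as.character(seqnames(gr)), start(gr))

#' Partition SNP sites into donor-specific, recipient-specific and shared
#'
#' A site is donor-specific iff its alternate allele appears in the donor
#' table and not in the recipient table at the same position (and vice
#' versa); a site whose alternate allele appears in both is shared and
#' excluded from both specific sets. Positions at which the two tables
#' disagree on the reference allele are discarded with a warning.
#'
#' When coverage evidence for the counterpart strain is supplied, absence of
#' its alternate allele only makes a site strain-specific if the counterpart
#' demonstrably covered the position — the same absence-handling rule the
#' congenic classification applies. Without coverage information, plain
#' table absence is used (expression dropout in the counterpart then leaks
#' some shared sites into the specific sets).
#'
#' @param donor,recipient \linkS4class{StrainVariants} on the same
#'   reference coordinates, already quality-filtered.
#' @param donorCovered,recipientCovered optional \code{GRanges} of sites
#'   each parental data set covered (e.g.
#'   \code{\link{coveredSites}}); positions with a variant record count as
#'   covered automatically.
#' @return list with \code{GRanges} elements \code{donorSpecific},
#'   \code{recipientSpecific} (mcols \code{ref}, \code{alt}) and
#'   \code{shared}.
#' @export
strainSpecificSites <- function(donor, recipient, donorCovered = NULL,
                                recipientCovered = NULL) {
  stopifnot(is(donor, "StrainVariants"), is(recipient, "StrainVariants"))
  d <- donor@calls; r <- recipient@calls
  dk <- siteKey(d); rk <- siteKey(r)
  m <- match(dk, rk)
  both <- which(!is.na(m))
  conflict <- unique(dk[both][mcols(d)$ref[both] !=
                                mcols(r)$ref[m[both]]])
  if (length(conflict)) {
    warning(length(conflict),
            " site(s) discarded: conflicting reference alleles")
    d <- d[!(dk %in% conflict)]; r <- r[!(rk %in% conflict)]
    dk <- siteKey(d); rk <- siteKey(r)
  }
  dAllele <- paste(dk, mcols(d)$alt)
  rAllele <- paste(rk, mcols(r)$alt)
  sharedAllele <- intersect(dAllele, rAllele)
  donorSpecific <- d[!(dAllele %in% sharedAllele)]
  recipientSpecific <- r[!(rAllele %in% sharedAllele)]
  shared <- d[dAllele %in% sharedAllele]
  if (!is.null(recipientCovered)) {
    covk <- unique(c(siteKey(recipientCovered), rk))
    donorSpecific <- donorSpecific[siteKey(donorSpecific) %in% covk]
  }
  if (!is.null(donorCovered)) {
    covk <- unique(c(siteKey(donorCovered), dk))
    recipientSpecific <-
      recipientSpecific[siteKey(recipientSpecific) %in% covk]
  }
  keepCols <- function(g) {
    out <- granges(g)
    mcols(out) <- DataFrame(ref = mcols(g)$ref, alt = mcols(g)$alt)
    out
  }
  list(donorSpecific = keepCols(donorSpecific),
       recipientSpecific = keepCols(recipientSpecific),
       shared = keepCols(shared))
}

#' Label congenic SNP sites by strain of origin
#'
#' At each donor-specific site: the congenic table carrying the matching
#' donor alternate allele is donor-informative evidence; a missing record at
#' a site the congenic data demonstrably covers means the reference
#' (recipient) allele and is recipient-informative; a missing record with
#' unknown coverage is uninformative, because RNA-Seq expression dropout
#' makes raw absence ambiguous. The converse logic applies at
#' recipient-specific sites.
#'
#' @param congenic \linkS4class{StrainVariants} for the congenic strain.
#' @param donorSpecific,recipientSpecific site sets from
#'   \code{\link{strainSpecificSites}}.
#' @param covered optional \code{GRanges} of congenic-covered sites (from
#'   the observation model or a coverage track); when NULL, no absence is
#'   ever treated as reference evidence.
#' @return \code{GRanges} of all informative-candidate sites with mcols
#'   \code{origin} (factor: donor_informative, recipient_informative,
#'   uninformative), \code{site_class}, \code{ref}, \code{alt}
#'   (the strain-specific alternate allele) and \code{congenic_allele}.
#' @export
classifyCongenicOrigin <- function(congenic, donorSpecific,
                                   recipientSpecific, covered = NULL) {
  stopifnot(is(congenic, "StrainVariants"))
  cg <- congenic@calls
  ck <- siteKey(cg)
  covk <- if (is.null(covered)) character(0) else siteKey(covered)
  classifyOne <- function(sites, siteClass) {
    n <- length(sites)
    if (n == 0L) {
      out <- GRanges()
      mcols(out) <- DataFrame(origin = factor(character(0),
        levels = c("donor_informative", "recipient_informative",
                   "uninformative")),
        site_class = character(0), ref = character(0), alt = character(0),
        congenic_allele = character(0))
      return(out)
    }
    sk <- siteKey(sites)
    m <- match(sk, ck)
    hasRec <- !is.na(m)
    matchAlt <- hasRec & mcols(cg)$alt[m] == mcols(sites)$alt
    coveredHere <- sk %in% covk
    matchLabel <- if (siteClass == "donor_specific")
      "donor_informative" else "recipient_informative"
    absentLabel <- if (siteClass == "donor_specific")
      "recipient_informative" else "donor_informative"
    origin <- rep("uninformative", n)
    origin[matchAlt] <- matchLabel
    origin[!hasRec & coveredHere] <- absentLabel
    out <- granges(sites)
    mcols(out) <- DataFrame(
      origin = factor(origin, levels = c("donor_informative",
        "recipient_informative", "uninformative")),
      site_class = siteClass,
      ref = mcols(sites)$ref, alt = mcols(sites)$alt,
      congenic_allele = ifelse(hasRec, mcols(cg)$alt[m],
                               ifelse(coveredHere, mcols(sites)$ref,
                                      NA_character_)))
    out
  }
  out <- c(classifyOne(donorSpecific, "donor_specific"),
           classifyOne(recipientSpecific, "recipient_specific"))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Candidate SNPs for consequence annotation
#'
#' Returns the SNPs inside a congenic locus whose alternate allele is
#' present in both the donor and the congenic strain and absent from the
#' recipient — the set considered possibly associated with the introgressed
#' phenotype.
#'
#' @param donor,recipient,congenic \linkS4class{StrainVariants}.
#' @param loci data.frame of congenic segments with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open bp), e.g. from
#'   \code{\link{detectSegments}}.
#' @return \code{GRanges} with mcols \code{ref}, \code{alt}.
#' @export
candidateSnpFilter <- function(donor, recipient, congenic, loci) {
  emptyOut <- function() {
    out <- GRanges()
    mcols(out) <- DataFrame(ref = character(0), alt = character(0))
    out
  }
  if (is.null(loci) || nrow(loci) == 0L) {
    warning("no congenic loci supplied; candidate SNP set is empty")
    return(emptyOut())
  }
  d <- donor@calls; r <- recipient@calls; cg <- congenic@calls
  dAllele <- paste(siteKey(d), mcols(d)$alt)
  rAllele <- paste(siteKey(r), mcols(r)$alt)
  cAllele <- paste(siteKey(cg), mcols(cg)$alt)
  keep <- cAllele %in% dAllele & !(cAllele %in% rAllele)
  cand <- cg[keep]
  lociGr <- GRanges(loci$chrom, IRanges(loci$start + 1, loci$end))
  inLocus <- GenomicRanges::countOverlaps(granges(cand), lociGr,
                                          ignore.strand = TRUE) > 0L
  cand <- cand[inLocus]
  out <- granges(cand)
  mcols(out) <- DataFrame(ref = mcols(cand)$ref, alt = mcols(cand)$alt)
  out
}
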