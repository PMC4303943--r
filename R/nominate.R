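## Candidate-gene assembly: genes polymorphic inside a congenic locus
## (missense candidate SNPs) united with DE genes whose bodies lie in a
## locus, with the overlap between the two evidence classes reported.

#' Cross-reference DE genes with congenic segments
#'
#' @param deGenes character vector of DE gene ids (e.g.
#'   \code{deFilter(...)$gene_id}).
#' @param segments data.frame of congenic segments (\code{chrom},
#'   \code{start}, \code{end}, half-open bp).
#' @param gms a \linkS4class{GeneModelSet} providing gene coordinates;
#'   DE genes absent from it are skipped with a warning.
#' @param mode \code{"any"} (default): any overlap of the gene body with a
#'   segment qualifies; \code{"within"}: the gene body must lie entirely
#'   inside a segment.
#' @return character vector of DE-in-locus gene ids, ordered by position.
#' @export
crossReference <- function(deGenes, segments, gms,
                           mode = c("any", "within")) {
  mode <- match.arg(mode)
  if (length(deGenes) == 0L || is.null(segments) || nrow(segments) == 0L)
    return(character(0))
  ids <- mcols(gms@genes)$gene_id
  missing <- setdiff(deGenes, ids)
  if (length(missing))
    warning(length(missing),
            " DE gene(s) lack gene-model coordinates and were skipped")
  keep <- gms@genes[ids %in% deGenes]
  segGr <- GRanges(segments$chrom,
                   IRanges(segments$start + 1, segments$end))
  ov <- findOverlaps(granges(keep), segGr,
                     type = if (mode == "within") "within" else "any",
                     ignore.strand = TRUE)
  hit <- keep[unique(queryHits(ov))]
  hit <- hit[order(as.factor(seqnames(hit)), start(hit))]
  as.character(mcols(hit)$gene_id)
}

#' Assemble the candidate-gene set for one congenic strain
#'
#' Polymorphic candidates are the genes carrying at least one missense
#' candidate SNP inside a congenic locus (nonsense and synonymous records
#' do not qualify); DE-in-locus candidates come from
#' \code{\link{crossReference}}. The union and the overlap between the two
#' evidence classes are reported explicitly.
#'
#' @param consequenceRecords data.frame from
#'   \code{\link{annotateCandidates}} (already restricted to locus-resident
#'   candidate SNPs).
#' @param deInLocus character vector of DE-in-locus gene ids.
#' @param strainLabel label for the report.
#' @param gms optional \linkS4class{GeneModelSet} used to order genes by
#'   position (alphabetical otherwise).
#' @return list of class \code{CandidateSet}: \code{strain},
#'   \code{polymorphic}, \code{deInLocus}, \code{overlap}, \code{union},
#'   \code{evidence} (per-gene table).
#' @export
nominateCandidates <- function(consequenceRecords, deInLocus,
                               strainLabel = "congenic", gms = NULL) {
  mis <- consequenceRecords[
    consequenceRecords$consequence_class == "missense", , drop = FALSE]
  polymorphic <- unique(mis$gene_id)
  deInLocus <- unique(as.character(deInLocus))
  overlap <- intersect(polymorphic, deInLocus)
  un <- union(polymorphic, deInLocus)
  un <- orderGenes(un, gms)
  evidence <- data.frame(
    gene_id = un,
    polymorphic = un %in% polymorphic,
    de_in_locus = un %in% deInLocus,
    n_missense_snps = vapply(un, function(g)
      sum(mis$gene_id == g), integer(1)),
    row.names = NULL)
  structure(list(strain = strainLabel,
                 polymorphic = orderGenes(polymorphic, gms),
                 deInLocus = orderGenes(deInLocus, gms),
                 overlap = orderGenes(overlap, gms),
                 union = un, evidence = evidence),
            class = "CandidateSet")
}

orderGenes <- function(ids, gms) {
  if (length(ids) == 0L) return(character(0))
  if (is.null(gms)) return(sort(ids))
  all <- mcols(gms@genes)$gene_id
  known <- ids[ids %in% all]
  g <- gms@genes[match(known, all)]
  ordered <- known[order(as.factor(seqnames(g)), start(g))]
  c(ordered, sort(setdiff(ids, known)))
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet for strain '%s'\n", x$strain))
  cat(sprintf("  polymorphic in locus : %d gene(s)\n",
              length(x$polymorphic)))
  cat(sprintf("  DE inside locus      : %d gene(s)\n",
              length(x$deInLocus)))
  cat(sprintf("  overlap              : %d gene(s)\n", length(x$overlap)))
  cat(sprintf("  union                : %d gene(s)\n", length(x$union)))
  invisible(x)
}

#' Write the candidate report as TSV plus a human-readable summary
#'
#' @param cs a \code{CandidateSet}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCandidateReport <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "candidates.tsv")
  txt <- file.path(dir, "candidates.txt")
  utils::write.table(cs$evidence, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- c(sprintf("Candidate genes for strain '%s'", cs$strain),
             sprintf("Polymorphic-in-locus (%d): %s",
                     length(cs$polymorphic),
                     paste(cs$polymorphic, collapse = ", ")),
             sprintf("DE-in-locus (%d): %s", length(cs$deInLocus),
                     paste(cs$deInLocus, collapse = ", ")),
             sprintf("Overlap of the two classes (%d): %s",
                     length(cs$overlap),
                     if (length(cs$overlap)) paste(cs$overlap,
                                                   collapse = ", ")
                     else "none"),
             sprintf("Union (%d)", length(cs$union)))
  writeLines(lines, txt)
  invisible(c(tsv, txt))
}
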