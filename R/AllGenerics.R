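#' Accessors for introscan classes
#'
#' @param x an introscan object.
#' @return \code{strain} returns the strain label; \code{variantCalls} the
#'   underlying \code{GRanges} of calls; \code{mosaicSegments} the ancestry
#'   segments; \code{donorRegions} the donor-origin subset;
#'   \code{geneRanges}, \code{cdsRanges} and \code{codingSeqs} the components
#'   of a \linkS4class{GeneModelSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strain", function(x) standardGeneric("strain"))

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname accessors
#' @export
setGeneric("mosaicSegments", function(x) standardGeneric("mosaicSegments"))

#' @rdname accessors
#' @export
setGeneric("donorRegions", function(x) standardGeneric("donorRegions"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname accessors
#' @export
setGeneric("codingSeqs", function(x) standardGeneric("codingSeqs"))

#' @rdname accessors
setMethod("strain", "StrainVariants", function(x) x@strain)

#' @rdname accessors
setMethod("variantCalls", "StrainVariants", function(x) x@calls)

#' @rdname accessors
setMethod("mosaicSegments", "GenomeMosaic", function(x) x@segments)

#' @rdname accessors
setMethod("donorRegions", "GenomeMosaic", function(x)
  x@segments[mcols(x@segments)$origin == "donor"])

#' @rdname accessors
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname accessors
setMethod("cdsRanges", "GeneModelSet", function(x) x@cds)

#' @rdname accessors
setMethod("codingSeqs", "GeneModelSet", function(x) x@codingSeq)

#' @rdname accessors
#' @aliases length,StrainVariants-method
setMethod("length", "StrainVariants", function(x) length(x@calls))

#' @rdname accessors
#' @aliases length,GeneModelSet-method
setMethod("length", "GeneModelSet", function(x) length(x@genes))

setMethod("show", "StrainVariants", function(object) {
  cat(sprintf("StrainVariants: %d SNV call(s) for strain '%s'\n",
              length(object@calls), object@strain))
  if (length(object@calls))
    cat(sprintf("  chromosomes: %s; QUAL range: [%g, %g]\n",
                paste(seqlevels(object@calls), collapse = ", "),
                min(mcols(object@calls)$qual),
                max(mcols(object@calls)$qual)))
})

setMethod("show", "GenomeMosaic", function(object) {
  seg <- object@segments
  don <- sum(width(seg)[mcols(seg)$origin == "donor"])
  cat(sprintf(paste0("GenomeMosaic: %d segment(s) on %d chromosome(s); ",
                     "donor fraction %.4f\n"),
              length(seg), length(seqlevels(seg)),
              don / sum(as.numeric(seqlengths(seg)))))
})

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d gene model(s), total CDS %.3f Mbp\n",
              length(object@genes),
              sum(as.numeric(sum(width(object@cds)))) / 1e6))
})

setMethod("show", "BreedingModel", function(object) {
  cat(sprintf(paste0("BreedingModel: N = %d backcrosses, %g bp/cM, ",
                     "%d chromosome(s), %d selected marker(s)\n"),
              object@nBackcrosses, object@bpPerCM,
              nrow(object@chromosomes), length(object@selectedMarkers)))
})

#' Fraction of the genome (or one chromosome) that is donor-origin
#'
#' @param x a \linkS4class{GenomeMosaic}.
#' @param chrom optional chromosome name; when NULL the genome-wide fraction
#'   is returned.
#' @return numeric fraction in [0, 1].
#' @export
donorFraction <- function(x, chrom = NULL) {
  stopifnot(is(x, "GenomeMosaic"))
  seg <- x@segments
  if (!is.null(chrom)) seg <- seg[seqnames(seg) == chrom]
  tot <- if (is.null(chrom)) sum(as.numeric(seqlengths(x@segments)))
         else as.numeric(seqlengths(x@segments)[[chrom]])
  sum(as.numeric(width(seg))[mcols(seg)$origin == "donor"]) / tot
}
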