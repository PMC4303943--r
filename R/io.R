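## Readers and writers for the external formats the pipeline touches.
## External conventions: VCF and GFF3 are 1-based inclusive; bin and segment
## edges elsewhere in the package are 0-based half-open bp values.

#' @importFrom VariantAnnotation readVcf expand ref alt qual
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom rtracklayer import export
NULL

## ---- VCF -------------------------------------------------------------------

#' Read a strain VCF, applying the quality and SNV filters
#'
#' Parses a VCF 4.2 subset through \pkg{VariantAnnotation}, splits
#' multi-allelic records (or rejects them), and retains biallelic
#' single-nucleotide records with \code{QUAL >= minQual}. The default
#' threshold of 100 is the pileup consensus-quality cutoff used when the
#' calls were produced; records failing it, indels, and records with missing
#' QUAL are dropped and the counts reported via \code{message()}.
#'
#' @param path VCF file.
#' @param strainLabel strain label; defaults to the file name stem.
#' @param minQual minimum QUAL retained (records at exactly the threshold
#'   are kept).
#' @param multiallelic \code{"split"} (default) to expand multi-allelic
#'   records into biallelic ones, \code{"reject"} to error on them.
#' @return a \linkS4class{StrainVariants}.
#' @export
readStrainVcf <- function(path, strainLabel = NULL, minQual = 100,
                          multiallelic = c("split", "reject")) {
  multiallelic <- match.arg(multiallelic)
  if (is.null(strainLabel))
    strainLabel <- sub("\\.vcf$", "", basename(path))
  checkVcfLines(path, multiallelic)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  v <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(v)
  refs <- as.character(ref(v))
  alts <- as.character(alt(v))
  quals <- qual(v)
  isSnv <- nchar(refs) == 1L & nchar(alts) == 1L &
    refs %in% VALID_BASES & alts %in% VALID_BASES & refs != alts
  passQual <- !is.na(quals) & quals >= minQual
  keep <- isSnv & passQual
  nDropSnv <- sum(!isSnv)
  nDropQual <- sum(isSnv & !passQual)
  if (nDropSnv + nDropQual > 0L)
    message(sprintf(
      "%s: dropped %d non-SNV and %d low-QUAL record(s) (QUAL < %g)",
      basename(path), nDropSnv, nDropQual, minQual))
  strainVariants(as.character(seqnames(rr))[keep], start(rr)[keep],
                 refs[keep], alts[keep], quals[keep],
                 strain = strainLabel)
}

## Structural pre-check so that malformed input fails with a line number
## instead of an opaque parser error.
checkVcfLines <- function(path, multiallelic = "split") {
  lines <- readLines(path)
  isMeta <- startsWith(lines, "##")
  header <- which(startsWith(lines, "#CHROM"))
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat"))
    stop("line 1: missing ##fileformat header in ", path)
  if (length(header) != 1L)
    stop("expected exactly one #CHROM header line in ", path)
  body <- which(!isMeta & !startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("line ", i, ": expected >= 8 tab-separated fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[2L]))))
      stop("line ", i, ": POS is not an integer: '", f[2L], "'")
    if (multiallelic == "reject" && grepl(",", f[5L], fixed = TRUE))
      stop("line ", i, ": multi-allelic record rejected by configuration")
  }
  invisible(TRUE)
}

#' Write StrainVariants as a VCF 4.2 subset
#'
#' @param x a \linkS4class{StrainVariants} or
#'   \linkS4class{StrainObservation}.
#' @param path output file.
#' @param seed optional integer recorded in the header for provenance.
#' @return \code{path}, invisibly.
#' @export
writeStrainVcf <- function(x, path, seed = NULL) {
  if (is(x, "StrainObservation")) x <- x@calls
  stopifnot(is(x, "StrainVariants"))
  gr <- x@calls
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introscan",
           sprintf("##introscan_strain=%s", x@strain))
  if (!is.null(seed))
    hdr <- c(hdr, sprintf("##introscan_seed=%d", as.integer(seed)))
  sl <- seqlengths(gr)
  for (chr in names(sl))
    if (!is.na(sl[[chr]]))
      hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", chr, sl[[chr]]))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", sep = "\t"))
  recs <- if (length(gr)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.",
            as.character(seqnames(gr)), start(gr), mcols(gr)$ref,
            mcols(gr)$alt, formatC(mcols(gr)$qual, format = "fg"))
  } else character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read/write the covered-site table accompanying a strain VCF
#'
#' Two-column TSV (\code{chrom}, \code{pos}, 1-based) listing every site
#' with observation evidence, emitted by \code{\link{observeVariants}}.
#'
#' @param x \code{GRanges} of covered sites (or a
#'   \linkS4class{StrainObservation}).
#' @param path file path.
#' @return \code{readCoveredSites} returns a \code{GRanges}.
#' @export
writeCoveredSites <- function(x, path) {
  if (is(x, "StrainObservation")) x <- x@covered
  utils::write.table(
    data.frame(chrom = as.character(seqnames(x)), pos = start(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoveredSites
#' @export
readCoveredSites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  GRanges(df$chrom, IRanges(as.integer(df$pos), width = 1L))
}

## ---- GFF3 + FASTA ----------------------------------------------------------

#' Read gene models from a GFF3 subset and a genome FASTA
#'
#' Expects gene/mRNA/CDS features linked by ID/Parent. CDS intervals are
#' stitched in transcript orientation and minus-strand sequence is
#' reverse-complemented into coding orientation. Models whose total CDS
#' length is not a multiple of 3, or whose CDS intervals overlap, are
#' excluded with a warning.
#'
#' @param gffPath GFF3 file.
#' @param fastaPath genome FASTA with one sequence per chromosome.
#' @return a \linkS4class{GeneModelSet}.
#' @export
readGeneModels <- function(gffPath, fastaPath) {
  gff <- rtracklayer::import(gffPath, format = "gff3")
  genome <- readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  geneRows <- gff[gff$type == "gene"]
  mrnaRows <- gff[gff$type == "mRNA"]
  cdsRows <- gff[gff$type == "CDS"]
  mrnaParent <- stats::setNames(
    vapply(mrnaRows$Parent, `[`, character(1), 1L), mrnaRows$ID)
  geneSymbol <- stats::setNames(
    if (!is.null(geneRows$Name)) geneRows$Name else geneRows$ID,
    geneRows$ID)
  cdsGene <- mrnaParent[vapply(cdsRows$Parent, `[`, character(1), 1L)]
  keepIds <- character(0); cdsList <- list(); seqList <- list()
  for (id in unique(cdsGene)) {
    cds <- cdsRows[cdsGene == id]
    cds <- cds[order(start(cds))]
    minus <- as.character(strand(cds)[1L]) == "-"
    if (minus) cds <- rev(cds)     # transcript orientation
    tot <- sum(width(cds))
    if (sum(width(GenomicRanges::reduce(cds, ignore.strand = TRUE))) != tot) {
      warning("gene ", id, ": overlapping CDS intervals; model excluded")
      next
    }
    if (tot %% 3L != 0L) {
      warning("gene ", id, ": CDS length ", tot,
              " not a multiple of 3; model excluded")
      next
    }
    chrSeq <- genome[[as.character(seqnames(cds))[1L]]]
    pieces <- lapply(seq_along(cds), function(j)
      subseq(chrSeq, start(cds)[j], end(cds)[j]))
    spliced <- do.call(Biostrings::xscat,
                       if (minus) lapply(rev(pieces), identity) else pieces)
    if (minus) spliced <- reverseComplement(spliced)
    keepIds <- c(keepIds, id)
    cdsList[[id]] <- granges(cds)
    seqList[[id]] <- spliced
  }
  if (length(keepIds) == 0L) stop("no valid gene model in ", gffPath)
  genes <- geneRows[match(keepIds, geneRows$ID)]
  gr <- granges(genes)
  mcols(gr) <- DataFrame(gene_id = keepIds,
                         symbol = unname(geneSymbol[keepIds]))
  seqs <- DNAStringSet(seqList)
  names(seqs) <- keepIds
  new("GeneModelSet", genes = gr, cds = GRangesList(cdsList),
      codingSeq = seqs)
}

#' Write gene models as GFF3 (and optionally the genome FASTA)
#'
#' @param gms a \linkS4class{GeneModelSet}.
#' @param gffPath output GFF3 path.
#' @param fastaPath optional FASTA path for the genome sequence.
#' @param genome optional \code{DNAStringSet} named by chromosome; built
#'   with \code{\link{genomeSequences}} when omitted and
#'   \code{fastaPath} is given.
#' @return \code{gffPath}, invisibly.
#' @export
writeGeneModels <- function(gms, gffPath, fastaPath = NULL, genome = NULL) {
  stopifnot(is(gms, "GeneModelSet"))
  ids <- mcols(gms@genes)$gene_id
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    g <- gms@genes[i]
    txid <- paste0(id, ".t1")
    gene <- granges(g)
    mcols(gene) <- DataFrame(type = "gene", ID = id,
                             Name = mcols(gms@genes)$symbol[i],
                             Parent = NA_character_,
                             phase = NA_integer_)
    mrna <- gene
    mcols(mrna) <- DataFrame(type = "mRNA", ID = txid,
                             Name = NA_character_, Parent = id,
                             phase = NA_integer_)
    cds <- gms@cds[[id]]
    priorLen <- cumsum(c(0L, width(cds)))[seq_along(cds)]
    mcols(cds) <- DataFrame(type = "CDS",
                            ID = paste0(txid, ".cds", seq_along(cds)),
                            Name = NA_character_, Parent = txid,
                            phase = (3L - priorLen %% 3L) %% 3L)
    rows[[i]] <- c(gene, mrna, cds)
  }
  out <- do.call(c, rows)
  mcols(out)$Parent <- ifelse(is.na(mcols(out)$Parent), "",
                              mcols(out)$Parent)
  rtracklayer::export(out, gffPath, format = "gff3")
  if (!is.null(fastaPath)) {
    if (is.null(genome)) {
      sl <- seqlengths(gms@genes)
      genome <- genomeSequences(gms, sl)
    }
    writeXStringSet(genome, fastaPath)
  }
  invisible(gffPath)
}

#' Materialize chromosome sequences consistent with a GeneModelSet
#'
#' Fills each chromosome with 'A' and lays the coding sequence of every gene
#' onto its CDS intervals (reverse-complemented for minus-strand genes).
#' Intended for test-scale genomes; chromosome-scale mosaics are analysed
#' without materializing sequence.
#'
#' @param gms a \linkS4class{GeneModelSet}.
#' @param chromLengths named chromosome lengths (bp).
#' @return a \code{DNAStringSet} named by chromosome.
#' @export
genomeSequences <- function(gms, chromLengths) {
  stopifnot(!any(is.na(chromLengths)))
  chroms <- lapply(chromLengths, function(n)
    paste(rep("A", n), collapse = ""))
  ids <- mcols(gms@genes)$gene_id
  for (i in seq_along(ids)) {
    cds <- gms@cds[[ids[i]]]
    chr <- as.character(seqnames(cds))[1L]
    minus <- as.character(strand(cds))[1L] == "-"
    seq <- gms@codingSeq[[ids[i]]]
    offs <- cumsum(c(0L, width(cds)))
    for (j in seq_along(cds)) {
      chunk <- subseq(seq, offs[j] + 1L, offs[j + 1L])
      if (minus) chunk <- reverseComplement(chunk)
      substr(chroms[[chr]], start(cds)[j], end(cds)[j]) <-
        as.character(chunk)
    }
  }
  DNAStringSet(unlist(chroms))
}

## ---- count tables ----------------------------------------------------------

#' Read or write a gene x sample count table (TSV)
#'
#' Rectangular, header row of sample ids, first column of gene ids;
#' counts must be non-negative integers.
#'
#' @param path TSV file.
#' @return \code{readCountMatrix} returns an integer matrix with gene
#'   rownames.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("count table needs gene ids plus >= 1 sample")
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(m)) stop("count table contains missing or ragged entries")
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0)) stop("negative counts are not allowed")
  if (any(m != round(m))) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname readCountMatrix
#' @param counts integer matrix of counts.
#' @export
writeCountMatrix <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- validation entry point ------------------------------------------------

#' Validate an input file against its expected format
#'
#' Dispatches on file extension (\code{.vcf}, \code{.gff3}/\code{.gff},
#' \code{.tsv}) unless \code{type} is given. Errors describe the first
#' problem found; returns \code{TRUE} invisibly on success.
#'
#' @param path file to validate.
#' @param type one of \code{"auto"}, \code{"vcf"}, \code{"counts"},
#'   \code{"covered"}.
#' @export
validateFile <- function(path, type = c("auto", "vcf", "counts",
                                        "covered")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (type == "auto") {
    ext <- tolower(tools::file_ext(path))
    type <- switch(ext, vcf = "vcf", tsv = "counts",
                   stop("cannot infer format of ", path))
  }
  switch(type,
    vcf = checkVcfLines(path),
    counts = invisible(readCountMatrix(path)),
    covered = invisible(readCoveredSites(path)))
  invisible(TRUE)
}
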