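#' Simulate a negative-binomial RNA-Seq count matrix with designated DE genes
#'
#' Per-gene base means are drawn log-uniformly on \code{nbMeanRange}; counts
#' are NB(mu, alpha) with \code{var = mu + alpha * mu^2}. A fraction
#' \code{deFraction} of genes is differentially expressed: their group-2 mean
#' is the base mean scaled by \code{2^log2fc}, with log2fc sampled from
#' \code{deLog2fc}.
#'
#' @param spec a \linkS4class{CountSimSpec}.
#' @return list with \code{counts} (integer matrix, genes x samples),
#'   \code{groups} (factor with levels \code{group1}, \code{group2}) and
#'   \code{truth} (data.frame gene_id, is_de, log2fc).
#' @export
#' @examples
#' sim <- simulateCounts(countSimSpec(nGenes = 100, seed = 3))
#' table(sim$truth$is_de)
simulateCounts <- function(spec) {
  stopifnot(is(spec, "CountSimSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nG <- spec@nGenes
  n1 <- spec@nSamplesPerGroup[1L]; n2 <- spec@nSamplesPerGroup[2L]
  mu <- exp(stats::runif(nG, log(spec@nbMeanRange[1L]),
                         log(spec@nbMeanRange[2L])))
  nDE <- round(spec@deFraction * nG)
  isDE <- rep(FALSE, nG)
  if (nDE > 0L) isDE[sample.int(nG, nDE)] <- TRUE
  lfc <- rep(0, nG)
  if (nDE > 0L)   # index-sample: robust to a length-1 deLog2fc
    lfc[isDE] <- spec@deLog2fc[sample.int(length(spec@deLog2fc), nDE,
                                          replace = TRUE)]
  size <- 1 / spec@nbDispersion
  counts1 <- matrix(stats::rnbinom(nG * n1, mu = rep(mu, n1), size = size),
                    nrow = nG)
  mu2 <- mu * 2^lfc
  counts2 <- matrix(stats::rnbinom(nG * n2, mu = rep(mu2, n2), size = size),
                    nrow = nG)
  counts <- cbind(counts1, counts2)
  rownames(counts) <- sprintf("gene%05d", seq_len(nG))
  colnames(counts) <- c(sprintf("g1_s%d", seq_len(n1)),
                        sprintf("g2_s%d", seq_len(n2)))
  groups <- factor(rep(c("group1", "group2"), c(n1, n2)),
                   levels = c("group1", "group2"))
  truth <- data.frame(gene_id = rownames(counts), is_de = isDE,
                      log2fc = lfc)
  list(counts = counts, groups = groups, truth = truth)
}
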