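---
title: "Mapping congenic loci and nominating candidate genes with introscan"
author: "introscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping congenic loci and nominating candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(introscan))
```

## The problem

A congenic strain is built by introgressing a chromosomal segment from a
donor inbred strain into a recipient inbred background through repeated
marker-selected backcrossing. After the process, the actual donor-origin
interval is never exactly the interval the markers were meant to bracket:
residual donor DNA flanks each selected marker, and occasionally the
transferred locus is a different one altogether. When the phenotype of the
congenic animal is the object of study — for example accelerated senescence
traits mapped to quantitative trait loci (QTLs) — knowing the true extent of
the introgressed segments is a precondition for any candidate-gene claim.

introscan delimits these segments from RNA-Seq-derived coding SNPs. The
idea: coding variants called from retinal (or any tissue) RNA of the donor,
the recipient, and the congenic strain can be compared as sets. A site whose
alternate allele occurs in the donor but not the recipient is
donor-informative wherever the congenic carries it; symmetrically for the
recipient. Binning informative sites along the chromosome paints the
congenic genome by ancestry, and runs of donor-dominated bins are the
introgressed segments. Candidate genes are then nominated on two independent
evidence classes: genes inside a segment carrying non-synonymous
donor-specific SNPs, and differentially expressed (DE) genes whose bodies
lie inside a segment.

Every stage is exercised on synthetic data with known ground truth, because
the original raw reads of such studies are frequently not deposited; the
package therefore ships a first-class generator for parental genomes,
breeding, RNA-Seq-style observation, and count matrices.

## The breeding model

Backcrossing is simulated under the Haldane (no-interference) model: per
meiosis the number of crossovers on a chromosome is Poisson with mean equal
to its genetic length in Morgans, breakpoints uniform on the centimorgan
scale. Both parents are inbred, so ancestry is haploid-trackable: the F1
contributes one whole-chromosome donor haplotype, and each generation
crosses the current haplotype against a pure recipient homolog, retaining
(by rejection sampling) a gamete that carries the donor allele at every
selected marker. Chromosomes without markers are transmitted without
selection, so their donor content halves per generation in expectation —
the classical (1/2)^N arithmetic.

Under this model the donor segment flanking a selected marker has
one-sided length distributed approximately Exp(N/100 cM^-1) after N
backcrosses, hence mean 100/N cM per side. `expectedFlanking()` returns the
closed form; `simulateFlankingCM()` verifies it by Monte Carlo with the same
meiosis engine. At N = 8 this gives 12.5 cM per side (25 cM in total),
converted at a uniform 2 Mbp per cM — the package applies one genome-wide
conversion constant and models no recombination hot or cold spots.

```{r flanking}
expectedFlanking(8)
```

## The synthetic genomes and their observation

`simulateParentalGenomes()` places gene models (1–3 CDS exons, total CDS a
multiple of 3, mean ~0.9 kb) along each chromosome to a target coding
fraction (default 0.05), then scatters divergent coding sites uniformly
within CDS at a default 15 sites per Mbp of chromosome. Half the divergent
sites carry the alternate allele in the donor, half in the recipient, plus
10% shared-alt sites at which both parents differ from the reference —
these exercise the shared-site exclusion path of the classifier. Defaults
for the observation model are 20% coverage dropout, 0.5% allele error,
true-call QUAL of 100 plus an exponential tail (mean 40), and error-call
QUAL uniform on [30, 150], so that the QUAL ≥ 100 filter removes part but
not all of the injected errors and is genuinely exercised.

What the generator emulates: the restriction of SNP visibility to expressed
transcripts (dropout), wrong-allele records with optimistic quality scores,
multi-allelic records (via the io layer), inbred homozygosity, and
NB-distributed count matrices. What it does not emulate: read-level
artifacts (mapping bias, splice-junction effects, allele-specific
expression), linkage between expression level and coverage depth, varying
SNP density along real chromosomes, and real dispersion heterogeneity
between genes. Passing tests therefore demonstrate the correctness and the
statistical behaviour of the algorithms under the stated model, not
end-to-end performance on real libraries.

## Origin classification and absence handling

`strainSpecificSites()` partitions sites by exact alternate-allele
comparison: donor-specific, recipient-specific, shared (excluded), with
sites discarded (warning) when the two tables disagree on the reference
base. `classifyCongenicOrigin()` then labels each strain-specific site by
the congenic evidence: a matching alternate record is informative for the
allele's strain; a missing record is informative for the *other* strain
only if the congenic data demonstrably covered the site; otherwise the site
is uninformative. Expression dropout makes raw absence ambiguous, and
treating it as reference evidence would paint phantom recipient segments
across unexpressed regions.

The same principle is available for the parental comparison itself
(`donorCovered`/`recipientCovered` arguments): without it, dropout in one
parent leaks shared-alt sites into the specific sets at roughly the dropout
x shared-fraction rate, which measurably contaminates donor bins with
false recipient-informative calls. The default remains the plain
set-difference rule; the pipeline passes coverage evidence wherever the
generator provides it.

## Segment detection

Informative calls are binned at 1 Mbp on the focal chromosome (10 Mbp for
genome-wide scans). Bin edges are 0-based half-open intervals; a position
exactly on an edge belongs to the bin starting there. A bin is
donor-labeled when it holds at least `minSupport = 3` donor-informative
SNPs and a donor fraction of at least `donorFraction = 0.8`; runs of donor
bins are merged across at most `maxGapBins = 2` bins that contain no
informative SNPs of either origin (expression deserts are gap-tolerated,
consistent with the absence-handling rule, rather than read as recipient
evidence). Segment boundaries are reported at bin resolution — the outer
edges of the terminal donor bins; sub-bin refinement is deliberately not
the default because a single informative SNP is weaker evidence than a
bin-level majority. The three knobs formalize what is otherwise a visual
judgement on binned SNP plots; a hidden-Markov alternative would smooth
boundaries but is left as future work.

## The differential-expression stage

The DE stage is intentionally minimal and self-contained:
median-of-ratios size factors, an exact conditional negative-binomial test
on the two group count sums, and Benjamini–Hochberg adjustment. Genes with
mean normalized count below 10 are excluded before testing. The strict DE
set uses padj < 0.1 with |log2FC| ≥ 1 (pseudocount 0.5 on the normalized
group means); a relaxed set replaces padj by the raw p-value at 0.05.

Dispersion is the one place where a naive design fails quantitatively:
per-gene method-of-moments estimates pooled across groups are unbiased in
the mean but so noisy at n = 3 per group that testing with them directly
inflates the null tail (we measured ~13% of null genes at p < 0.05).
The stage therefore fits a parametric mean–dispersion trend
alpha(mu) = a0 + a1/mu across genes by least squares and tests each gene at
its fitted, floored value. A robust (median-type) fit would sit below the
truth because the raw estimates are strongly right-skewed; the mean fit is
the calibrated choice, and with it the null fraction at p < 0.05 lands
within binomial error of 0.05 while the empirical FDR of the strict set
stays near its nominal level. Groups with a single sample (pooled
libraries) carry no replication: they are accepted only with a
user-supplied fixed dispersion, under a mandatory warning.

Two caveats are documented rather than hidden. First, the conditional test
on raw group sums is only approximately invariant to rescaling a sample's
counts (the normalized statistics are exactly invariant up to the global
size-factor normalization; the p-values correlate at rho > 0.85). Second,
gene lists will differ in detail from shrinkage-based tools; the stage is
validated by simulation properties (type-I error, FDR, power), not by list
identity with any external implementation, though an independent NB
reference implementation is used as a cross-check oracle in the test suite.

## Consequence annotation

`annotateConsequence()` maps a genomic SNP into a gene's coding sequence
(strand-aware; minus-strand alleles are complemented), substitutes the
alternate base in the affected codon, and translates both codons with the
standard nuclear code. Reported fields follow the conventions of standard
variant-effect annotation: 1-based CDS position, protein position
⌈CDS/3⌉, amino-acid change, and a codon-change string in which exactly the
substituted base is capitalized. The reported `allele` is the genomic
alternate base as variant tables print it — for minus-strand genes the
complement of the coding-strand base. Stop gains are classed `nonsense`
and never nominate candidates; selenocysteine and non-standard codes are
out of scope. SIFT scores are inputs, not computed: classification uses
the inclusive rule score ≤ 0.05 → deleterious, otherwise tolerated, with
missing scores reported as unscored.

```{r sift}
siftClassify(c(0, 0.05, 0.46, NA))
```

## Candidate nomination

`crossReference()` intersects DE gene bodies with detected segments (any
overlap by default; segments have bin-resolution boundaries, so requiring
full containment would drop edge genes arbitrarily — a `within` mode
exists). `nominateCandidates()` unites the polymorphic-in-locus genes
(≥ 1 missense candidate SNP inside a segment) with the DE-in-locus genes
and reports the overlap between the two classes explicitly; the report
totals satisfy |union| = |polymorphic| + |DE| − |overlap| and gene order is
deterministic (position, then name).

## Numerical and design choices, in brief

- GRanges (1-based, inclusive) is the internal container; all bin and
  segment edges exposed to the user are 0-based half-open bp values, with
  converters exercised in both directions by the tests.
- Multi-allelic VCF records are split into biallelic records by default
  (rejection is available); indels are excluded; genotype columns are
  ignored since inbred strains are homozygous.
- The exact NB test enumerates the conditional distribution of the group
  sum; totals beyond 1e5 fall back to a normal approximation.
- Seeds are explicit arguments everywhere; generated VCFs record the seed
  and strain in their headers; identical configuration and seed reproduce
  a pipeline run byte for byte (modulo the timestamped log).
- Monte-Carlo problem sizes used by the test suite: 10,000 breeding
  replicates for the flanking expectation; 200 replicates of the
  segment-recovery experiment on a 290-Mbp chromosome at 15 SNPs/Mbp;
  2,000-gene null and 50 x 1,000-gene mixed count simulations for the DE
  calibration. These sizes put the Monte-Carlo error well inside each
  check's tolerance while keeping a full run in minutes.
- In the segment-recovery experiment the parental variant sets enter as
  fully observed call tables and the congenic observation carries the
  noise; this isolates the observation process under study. The end-to-end
  pipeline demonstration instead passes all three strains through the
  noise model together with their coverage evidence.

## Limitations

Real RNA-Seq variant visibility correlates with expression level and
isoform structure, which the uniform dropout model ignores; segment
boundaries are only as sharp as the bin width; the DE stage assumes a
common mean–dispersion trend and two-group designs; and the candidate
report deliberately stops short of enrichment analysis against external
annotation services.

## A complete run

```{r run, eval = FALSE}
cfg <- studyLikeConfig(seed = 1)
res <- runPipeline(cfg, outDir = "introscan-run")
res$segments
cumulativeLength(res$segments)
res$flanking
print(res$candidates)
```
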