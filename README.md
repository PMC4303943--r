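# introscan

Congenic locus mapping and candidate-gene nomination from strain-specific
coding SNPs.

## What problem this solves

Interval-specific congenic strains — a donor chromosomal segment
introgressed into a recipient inbred background by N marker-selected
backcrosses — are the standard tool for confirming quantitative trait loci
(QTLs). But the segment actually transferred is never exactly the segment
intended: residual donor DNA averaging 100/N cM flanks each selected marker
(≈12.5 cM per side after 8 backcrosses, at ~2 Mbp/cM), and occasionally a
different locus is carried along entirely. Before any gene inside a
congenic locus can be called a candidate, the locus itself has to be
delimited.

introscan does this from RNA-Seq-derived coding SNPs, for geneticists
working with congenic rodent lines:

1. **Classify** each coding SNP site by strain of origin, comparing
   quality-filtered (QUAL ≥ 100) variant calls of donor, recipient, and
   congenic strains as sets: a site is donor-informative where the congenic
   carries an alternate allele found in the donor but not the recipient,
   and conversely. Absence of a record counts as reference evidence only at
   sites the congenic data demonstrably covered — RNA-Seq sees only
   expressed positions.
2. **Delimit** introgressed segments by binning informative SNPs (1 Mbp
   bins on the focal chromosome, 10 Mbp genome-wide) and merging runs of
   donor-dominated bins across SNP-free gaps; compare observed segment
   sizes with the breeding model's 100/N cM flanking expectation.
3. **Test** for differential expression with a self-contained
   negative-binomial stage: median-of-ratios normalization, exact
   conditional test on group sums with a fitted mean–dispersion trend,
   Benjamini–Hochberg adjustment, and the thresholds padj < 0.1 with
   |log2FC| ≥ 1 (relaxed mode: p < 0.05).
4. **Annotate** non-synonymous consequences of locus-resident SNPs — CDS
   position, protein position ⌈CDS/3⌉, amino-acid and codon change with
   the substituted base capitalized — and classify SIFT scores
   (≤ 0.05 deleterious, inclusive).
5. **Nominate** candidates: genes with missense candidate SNPs inside a
   segment, united with DE genes whose bodies overlap a segment, with the
   overlap between the two evidence classes reported explicitly.

A first-class synthetic-data module simulates divergent parental genomes,
Haldane-model marker-selected backcrossing, RNA-Seq variant observation
with coverage dropout and base-call error, and NB count matrices — all with
ground truth, so every stage is validated against what was planted. A
packaged table of published candidate SNPs (22 rows over 19 genes in two
congenic loci) serves as a golden input for the annotator.

## Worked example

Simulate a congenic chromosome whose donor-origin truth segments are
89.0–97.0, 104.0–105.1, 178.0–210.0 and 234.0–274.0 Mbp (81.1 Mbp in
total), observe the congenic strain with 20% coverage dropout and 0.5%
allele error, and recover the segments:

```r
library(introscan)

ex <- segmentRecoveryExperiment(nReps = 1, seed = 1)
ex$segments
#>   chrom    start      end n_donor_snps n_recipient_snps
#> 1  chr1 8.90e+07 9.70e+07           99                0
#> 2  chr1 1.04e+08 1.05e+08           25                0
#> 3  chr1 1.78e+08 2.10e+08          364                4
#> 4  chr1 2.34e+08 2.74e+08          489                3
cumulativeLength(ex$segments)
#> [1] 81
```

Three of the four truth segments are recovered at exact bin resolution and
the fourth (104.0–105.1 Mbp) at its bin-rounded extent; the cumulative
length of 81.0 Mbp sits 0.1 Mbp from the planted truth. The breeding
model's closed-form expectation for the residual flanking DNA:

```r
expectedFlanking(8)
#>   n_backcrosses per_side_cM total_cM per_side_bp
#> 1             8        12.5       25     2.5e+07
```

Annotating the first packaged candidate SNP (a missense variant at CDS
position 667 of the Hps5 gene, on the minus strand, so the reported
genomic allele C is the complement of the coding-strand G):

```r
t1  <- publishedCandidateSnps()
toy <- candidateToyGenome()
s   <- toy$snps[1, ]
annotateConsequence(toy$genes, s$gene_id, s$chrom, s$pos, s$ref, s$alt,
                    siftScore = t1$sift_score[1])
#>   gene_id symbol allele strand cds_position protein_position ref_aa alt_aa
#> 1 cand01   Hps5      C      -          667              223      R      G
#>   aa_change codon_change consequence_class sift_score sift_class
#> 1       R/G      Aga/Gga          missense       0.46  tolerated
```

The full pipeline — simulation, VCF/coverage/count I/O, classification,
segment detection, DE, annotation, nomination — runs from one
configuration:

```r
res <- runPipeline(studyLikeConfig(seed = 1), outDir = "introscan-run")
```

or from the shell via the thin front-end
`Rscript inst/scripts/introscan.R run --config cfg.yaml --out run/`
(subcommands `simulate`, `run`, `validate`).

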