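# svCohort

Cross-sample structural variant (SV) integration, annotation and genotype
analysis for long-read sequencing cohorts.

## The problem

Long-read callers such as Sniffles report insertions, deletions,
inversions, duplications and breakends (INS/DEL/INV/DUP/BND, ≥ 50 bp) one
sample at a time. To compare a cohort — for cultivar identification,
marker design, or population structure — the per-sample call sets must be
reconciled: the same ancestral SV is reported at slightly different
positions and lengths in different samples because of read noise and
alignment ambiguity. `svCohort` integrates per-sample SV VCFs into one
table of merged sites with a genotype (`0/0`, `0/1`, `1/1`) for **every**
sample at **every** site, then supports confidence filtering, primer-design
flank extraction, gene/upstream annotation, cohort statistics, genotype PCA
and chromosome-scale genotype maps. A fully seeded synthetic-cohort
simulator with truth-based recovery scoring makes the whole pipeline
testable without any sequencing data.

## The core rule

Two same-type calls on one chromosome may belong to the same site when
their positional offset does not exceed

```
T(a, b) = M * sqrt(min(len_a, len_b))        (M = 250 by default)
```

so larger SVs, whose breakpoints are harder to place exactly, tolerate
larger offsets. Calls are sorted by position and chained through
sorted-adjacent pairs within threshold (single linkage); each resulting
cluster becomes one merged site whose representative position and length
are the member medians, and whose dispersion statistics
`STDEV_POS`/`STDEV_LEN` (population SDs of member positions/lengths) feed
the confidence filter: a site is removed when either dispersion is ≥ 1, or
when it is flagged IMPRECISE (all thresholds configurable).

## Worked example

```r
library(svCohort)

genome <- simulateReference(2, 400000, seed = 42, path = "ref.fa")
truth  <- plantCohort(genome, nSites = 12, nSamples = 4, seed = 43)
vcfs   <- emitVcfs(truth, posJitterSd = 0.5, outDir = "vcfs", seed = 44)

calls  <- lapply(names(vcfs), function(s) readSampleCalls(vcfs[[s]], s))
names(calls) <- names(vcfs)
cohort <- mergeCohort(calls, M = 250)
cohort
#> SVCohort with 12 merged sites across 4 samples
#>   types: DEL:3 DUP:1 INS:7 INV:1
#>   chroms: chr1, chr2
#>   sequences attached: no
#>   merge constant M = 250

res    <- filterSites(cohort)           # STDEV_POS/STDEV_LEN >= 1, IMPRECISE
cohort <- attachSequences(res$cohort, genome, flank = 300)
tab    <- writeCohortTable(cohort, "sv_cohort_table.tsv")
tab[1:3, 1:10]
#>      Position Type Reliability Length Stdev_pos Stdev_len S01 S02 S03 S04
#> 1   chr1-2568  INV     PRECISE    757         0         0 0/0 0/1 0/0 0/0
#> 2  chr1-53940  INS     PRECISE    894         0         0 0/0 1/1 0/1 0/0
#> 3 chr1-106789  INS     PRECISE    457         0         0 0/1 0/0 0/0 1/1

chromosomeSummary(cohort, genome)
#>   chrom nSites lengthBp density nThreeGenotype densityDisplay
#> 1  chr1      7    4e+05    17.5              4           17.5
#> 2  chr2      5    4e+05    12.5              3           12.5
#> 3 Total     12    8e+05    15.0              7           15.0

scoreRecovery(truth, cohort)
#> recall 1.00  precision 1.00  genotype accuracy 1.000
```

Each row of the written table is one reference position: `chrom-pos`, the
SV type, reliability, representative length, the two dispersion values, one
genotype column per sample, then the SV sequence and 300 bp of upstream and
downstream reference flanks (the raw material for PCR primer design).
`writeGeneTable()` restricts the table to sites inside a gene body or
within the (strandless) 2,000 bp upstream window of a gene — truncated at
the end of the nearest preceding gene — and appends gene name, neighboring
genes, region label and the track's annotation columns. A merged site at
which all three genotypes occur across the cohort is a candidate
co-dominant marker; `selectMarkerCandidates()` applies the full selection
rule (INS/DEL, ≤ 1,000 bp, three genotypes, optional reference-sample
exclusion). `runGenotypePca()` encodes genotypes as 0/1/2 dosages and runs
centered, unit-variance PCA for sample-relatedness plots;
`buildPlotMatrix()`/`renderGenotypeMap()` draw the per-chromosome genotype
map with scaffold points every 50 kb.

A thin command-line wrapper with `all`, `simulate`, `pca` and `plot`
subcommands lives in `inst/scripts/sv-cohort-cli.R`.

## Bundled example data

`inst/extdata/citrus_*.tsv` carry the published summary tables of a
14-cultivar citrus cohort (per-chromosome site counts, per-cultivar
type/zygosity counts, and two 9-marker × 14-cultivar genotype grids:
sequencing-based calls and the genotypes read off electrophoresis band
patterns). They drive the concordance and ratio examples in the tests and
the acceptance script.

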