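---
title: "Integrating structural variants across a long-read cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating structural variants across a long-read cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svCohort)
```

## The model

A long-read SV caller reports, per sample, a set of calls: a chromosome, a
1-based anchor position, a type (INS, DEL, INV, DUP, or BND for breakpoints
of unresolved type), a length (undefined for BND), a genotype among `0/0`,
`0/1`, `1/1`, and a PRECISE/IMPRECISE confidence flag. The same underlying
variant surfaces at slightly different coordinates in different samples —
breakpoint placement depends on the reads and the aligner — so cross-sample
comparison needs a tolerance that grows with variant size. `svCohort`
merges two same-type calls when their positional offset is at most

$$T(a,b) = M \sqrt{\min(\ell_a, \ell_b)}$$

with merge constant $M$ (dimensionless, default 250). The square-root form
means a 100 bp variant tolerates a 2.5 kb offset while a 10 kb variant
tolerates 25 kb; raising $M$ relaxes every comparison, and $M = 0$ merges
only exact-position duplicates.

**Clustering.** Calls of one (chromosome, type) partition are sorted by
position and sorted-adjacent pairs within threshold are chained; clusters
are the connected components of this chain. This is single linkage
restricted to the sorted order: it is deterministic, $O(n \log n)$, and the
test suite pins its semantics against an independent union-find
connected-components oracle on the same adjacency. The choice is ours —
multi-sample callers do not document their clustering — and single linkage
was preferred because it never splits a run of mutually-close calls, which
is the behaviour the threshold formula implies. BND calls carry no length,
so BND pairs are compared with a fixed window of $M$ bp instead of the
formula; this is a documented deviation where the underlying convention is
silent.

**Summaries.** Each cluster becomes one merged site. The representative
position and length are the member medians (the lower of the two middles
for even counts, keeping representatives at observed values); medians
resist a single outlier sample. Dispersion is reported as the *population*
standard deviation of member positions and lengths: a singleton cluster —
an SV seen in one sample only, the common case — then reports 0 rather
than an undefined value, and survives the default filter. Every cohort
sample gets a genotype at every site; samples contributing no member carry
`0/0` ("no SV detected here"). When one sample contributes several calls to
a cluster, the call nearest the representative position wins, ties broken
toward the higher-alt genotype (preferring to report a variant over
half-reporting it); the losing calls remain members, so call conservation
(every input call in exactly one site) always holds.

## Confidence filtering

A merged site is removed when any of: `STDEV_POS` ≥ 1 bp, `STDEV_LEN` ≥ 1
bp, the site is flagged imprecise, or its representative length fell below
the 50 bp minimum after merging. The dispersion thresholds are inclusive
(exactly 1.0 is removed) and configurable; "imprecise" means *positively
flagged* — a record carrying neither flag is treated as precise, so the
filter can only ever act on caller-asserted uncertainty. For reproducible
reports each removed site is attributed to the first failing rule in the
fixed order above (the underlying criteria are an unordered "any", so the
order affects only the report breakdown, never the kept set).

## Flanks and gene annotation

For primer design each site carries its SV sequence and reference flanks
(default 300 bp per side). Coordinates follow the VCF anchor convention:
the anchor base at `pos` precedes the affected bases, so for a deletion the
SV sequence is `[pos+1, end]`, the upstream flank is the 300 bases ending
at `pos` inclusive, and the downstream flank starts at `end+1` —
concatenating the three reassembles a contiguous reference substring, which
the tests assert. Insertions sit between `pos` and `pos+1`; their SV
sequence is the inserted sequence of the member call nearest the
representative position (one sequence must be chosen per row; nearest is
the least arbitrary). Flanks truncate at contig boundaries rather than
erroring, so sites near chromosome ends degrade gracefully.

The gene track is a BED-like table — chromosome, gene id, start, end,
free-text annotation columns — with 0-based half-open coordinates assumed
(the BED standard; the conversion happens once at the reading boundary and
all interval logic uses that single convention). The track has no strand
column, so "upstream" necessarily means *lower coordinates*: a gene's
upstream region is the window of up to 2,000 bp (configurable) before its
start, truncated at the end of the nearest wholly-preceding gene and at
coordinate 0. A site is *genic* for every gene whose body intersects its
interval (`[pos, end]` for DEL/INV/DUP, the single anchor base for
INS/BND) and *upstream* for every gene whose upstream window intersects it
while the body does not — genic takes precedence per gene, and a site
spanning both window and body is genic only. An SV touching several genes
yields one context, hence one output row, per gene. Strand-aware promoter
logic is impossible with this input and is deliberately out of scope.

## Output tables

The cohort table is tab-separated with a plain header line: position
(`chrom-pos`), type, reliability, length (empty for BND — not 0, so
re-read histograms stay honest), the two dispersions, one genotype column
per sample in manifest order, then SV/upstream/downstream sequences. The
gene table appends gene, neighboring genes, region label and the
annotation columns, one row per (site, gene context). Writing is
byte-deterministic (binary-mode connections, `\n` endings, C-format
numbers); a CSV export reproduces the TSV cell-for-cell for spreadsheet
use. A multi-sample VCF export carries the same sites for interoperability
with standard tooling.

## Cohort statistics

Per-chromosome summaries report site counts, density per Mb (full
precision kept internally, two decimals for display) and the number of
*three-genotype sites* — sites where `0/0`, `0/1` and `1/1` all occur
across the cohort, the substrate for co-dominant markers. Per-sample
summaries count non-`0/0` sites by type and zygosity, with the identity
`total = hom + het = sum of type counts` guaranteed. Length histograms use
half-open 50 bp bins starting at 50, the last regular bin closed at
10,000, and a single overflow bin above it (bin-edge labels in the source
figure style do not disambiguate boundaries; half-open-with-closed-top is
fixed here and tested). Marker-candidate selection keeps INS/DEL sites of
at most 1,000 bp with all three genotypes, optionally excluding sites where
a designated reference-derived sample is homozygous-alt (a sample that *is*
the reference should not carry credible homozygous SVs against it).
Genotype concordance between two marker × sample grids reports per-marker
agreement rates and their unweighted mean; with equal denominators this
equals the pooled rate.

## Genotype PCA and the genotype map

Genotypes encode as dosages (0/1/2) and feed centered, unit-variance PCA
(`prcomp`, i.e. SVD of the standardized matrix). Sites constant across the
cohort have no variance to scale and are dropped, with the count reported.
Component signs are arbitrary; every test is sign-invariant. The
per-chromosome genotype map lays one row per site plus *scaffold points*
at 0, every 50 kb, and the chromosome end, so chromosomes render at
uniform physical scale; scaffold rows default to a distinct neutral color
(grey) rather than the `0/0` color, because "no site detected here" and
"site detected, this sample is 0/0" are different statements — a
configurable choice (`scaffoldDistinct = FALSE` blends them). A scaffold
point coinciding with a site position keeps only the site row. PNG output
is written pixel-exactly from the category matrix, making image bytes
deterministic.

## The synthetic cohort

The simulator generates what the pipeline consumes: a uniform-random
reference, a non-overlapping gene track whose inter-gene gaps are drawn
half below 2 kb (so upstream-window truncation is actually exercised),
planted SV sites, and per-sample Sniffles-dialect VCFs. Defaults emulate a
marker-design-scale experiment: 5 samples, 50 sites, lengths 50–1,000 bp
(the marker-relevant range), type mix 45/45/5/5 over INS/DEL/INV/DUP,
genotype frequencies 0.4/0.4/0.2 over `0/0`/`0/1`/`1/1`, every site forced
to carry at least one non-`0/0` sample (an unobserved site is not a call).
Positional/length noise is integer-rounded Gaussian jitter and records are
flagged IMPRECISE at a configurable rate.

One guard makes recovery a *deterministic* property instead of a
statistical one: planted sites must be spaced further apart than the
largest possible merge threshold, $250\sqrt{\max \ell} \approx 7.9$ kb at
the default length range (the default spacing is 50 kb). Planted sites can
then never co-cluster, so with zero jitter the merged cohort must equal
the truth exactly — recall, precision and genotype accuracy 1.0 — and any
deviation is a defect, not noise. Scoring matches merged sites to truth
one-to-one (same chromosome and type, positional difference within a
window, greedy by distance); an empty cohort reports precision 1.0 with a
degenerate-case flag.

What the simulator does *not* emulate: read-level evidence (coverage,
genotype likelihoods), repeat-induced systematic mis-calls, multi-allelic
sites, or correlated errors between samples. Passing tests therefore
demonstrate the integration, filtering, annotation and reporting logic —
not caller accuracy on real reads.

## Problem sizes and numerical choices

The test suite runs on deliberately small instances: clustering oracles on
30–100 calls, annotation oracles on ≤ 180 genes × 50 sites, end-to-end
recovery on 50 sites × 5 samples, PCA on ≤ 12 × 80 matrices — each chosen
as the smallest size at which the property is non-trivial, keeping the
full suite under a couple of minutes. Other fixed numerical choices:
deletion `SVLEN` is accepted signed or unsigned and stored absolute;
missing genotypes (`./.`) normalize to `0/0` with a warning (the genotype
vocabulary downstream has exactly three values, so no imputation is ever
needed); gene-track rows with `start >= end` or fewer than four columns
are rejected with warnings rather than failing the file; sub-sequence
requests beyond contig ends truncate; jittered insertion sequences are
trimmed or padded to the jittered length.

## Limitations

- Merging quality is bounded by the per-sample caller; no read evidence is
  re-examined and no genotypes are re-called.
- Dispersion statistics are computed across member calls (i.e. across
  samples); callers that report dispersion across supporting reads within
  a sample measure something related but not identical.
- "Upstream" is strandless by construction of the input format.
- Exact agreement with any specific multi-sample caller's merged output is
  not claimed; the clustering rule here is fixed, documented and
  oracle-tested instead.
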