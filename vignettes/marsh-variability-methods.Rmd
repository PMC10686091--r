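---
title: "Models and methods: MAG abundance, SNV profiling, and DGR diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: MAG abundance, SNV profiling, and DGR diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshvar)
```

marshvar is a strain-level analysis toolkit for metagenome-assembled
genomes (MAGs), built around the questions that arise when sulfur-cycling
populations are tracked across salt-marsh sediment samples from different
sites and vegetation zones: which bins are trustworthy, how abundant is
each population in each sample, how much nucleotide-level variation do
recruited reads reveal, which genomic islands are specific to a sample
group, and how much protein diversity can a diversity-generating
retroelement (DGR) write into its target gene. This vignette explains each
model, its assumptions, and the design decisions behind the defaults.

## MAG screening and sulfur guilds

A MAG with completeness $C$ (%) and contamination $X$ (%) gets the
composite quality score $Q = C - 5X$. A MAG is retained when $C > 90$,
$X < 5$, and $Q \ge 65$. The two primary gates are strict inequalities;
the score gate is inclusive. Sources differ on whether the score cutoff
is strict or inclusive; we use $\ge 65$, and note that for any MAG
passing both primary gates $Q > 65$ holds automatically, so the choice
only matters for tables where the score is reported in isolation.

Guilds are operational, defined purely by marker-gene presence:
sulfate-reducing bacteria (SRB) require the complete dissimilatory
sulfate-reduction pathway (*sat*, *aprA*, *aprB*, *dsrA*, *dsrB*);
sulfur oxidizers (SOX) require the truncated thiosulfate-oxidation
system (*soxA*, *soxX*, *soxY*, *soxZ*, *soxB*). Many genuine sulfur
oxidizers carry both repertoires because *dsrAB* runs in either
direction; distinguishing oxidative from reductive *dsrAB* types
requires dedicated phylogenetic typing that is out of scope here, so
`classify_sulfur_guild()` reports `SRB+SOX` and never silently picks a
side. The caller disambiguates, with the per-MAG missing-gene report as
support.

## GCPM abundance

The abundance of a MAG in a sample is expressed as genome copies per
million reads (GCPM): the length-weighted mean of its contigs' mean
per-base coverages, standardized by library size,

$$\bar C = \frac{\sum_i cov_i \, len_i}{\sum_i len_i}, \qquad
  \mathrm{GCPM} = \bar C \cdot \frac{10^6}{\text{library reads}}.$$

This is the verbal definition implemented directly on raw contig
lengths. Upstream quantifiers that estimate coverage through effective
lengths or reassignment of multi-mapping reads will differ slightly; we
deliberately use the transparent formula because it is exactly
reproducible from a coverage table. GCPM values below a detection
threshold (default 2) are masked as not detected — low-coverage
recruitment to a reference MAG is dominated by conserved-region
cross-mapping and is not evidence of presence. Bray–Curtis
dissimilarities between samples' GCPM profiles are provided as plumbing
for ordination; a pair of all-zero profiles has an undefined
dissimilarity and is reported as 0 with a warning rather than NaN.

## SNV calling, gene entropy, and hotspots

A pileup position is a single-nucleotide variant (SNV) when its depth is
at least `min_depth` (default 10) and its minor allele frequency — one
minus the major base's frequency — is at least `min_maf` (default 0.1).
Both thresholds are explicit flags; the defaults are conventional values
that make the caller conservative at typical 10–100× recruitment depth
(at depth 10 a 10% minor allele is one read, so the depth gate is the
binding constraint there). The caller is monotone: raising either
threshold can only remove calls.

Positional diversity is the Shannon entropy of the A/C/G/T frequency
vector in bits (0 for a single allele, 2 for a uniform site). Per gene
we report the SNV count, SNVs per kbp, and mean entropy over positions
with depth at least `min_depth`; genes with no covered position get a
flagged missing entropy, never a silent zero. Sample-level burden is
normalized as SNVs per 100,000 mapped reads so divergence can be
compared across unequal sequencing effort.

"Hotspot" genes — the handful of ORFs with outlier variability against
an otherwise uniform background — are flagged with the upper Tukey fence
(Q3 + 1.5 IQR of the per-gene SNVs/kbp distribution, R's default
quantile definition). The rule is deterministic and needs at least four
genes to be meaningful.

## Group-specific regions from coverage breadth

Genomic islands present in one sample group and absent in another show
up as long runs of windows where breadth of coverage (fraction of
positions with depth ≥ 1) is high in every sample of one group and near
zero in every sample of another. We scan 1 kb windows and call a window
differential when breadth ≥ 0.5 in all samples of at least one group
and ≤ 0.1 in all samples of at least one other; adjacent windows with
the identical presence/absence pattern merge, and merged regions shorter
than 5 kb are dropped. The breadth fences and window size are our
defaults — read-recruitment plots identify such regions qualitatively,
and these values recover multi-kilobase deletions cleanly while ignoring
isolated coverage dropouts. With 1 kb windows the reported boundaries
are correct to within one window of the true event.

## DGR detection

A DGR cassette consists of a reverse transcriptase (RT), a template
region (TR), and a near-identical variable region (VR) inside a target
ORF. Mutagenesis is adenine-specific: mismatches between TR and VR
concentrate at TR adenines. RT loci are an input (coordinates from any
annotation source); the package's contribution is the repeat-pair and
polarity analysis around them.

`find_repeat_pairs()` searches a window (default 20 kbp) around the RT
for ungapped repeat pairs: exact k-mer seeds (k = 12) are extended in
both directions with X-drop scoring (match +1, mismatch −3, drop 15),
trimmed to the maximal-scoring match-delimited extent. Because TR/VR
pairs are near-identical and collinear, ungapped alignment suffices;
gapped detection is deferred. Extension is deterministic, so results
are. A 12-mer seed requires one exact 12 bp run between mismatches,
which textbook TR/VR pairs (~80–150 bp, ~5–15 mismatches) almost always
contain; candidate pairs must reach 50 aligned bp at ≥ 80% identity,
which random sequence essentially never does (a 20 kb null contig
yields no pairs in ≥ 95% of seeds).

`assign_tr_vr()` orients a pair by adenine polarity — the fraction of
mismatch columns at which a member carries A. The member with higher
polarity is the TR; ties are rejected as unorientable. A cassette is
accepted with at least 4 mismatch columns, polarity ≥ 0.75, and the VR
inside an ORF on either strand (the VR's frame within the ORF is
recorded). The gates accept textbook DGRs and reject symmetric-mismatch
repeats; all are flags.

## Codon accessibility and diversity products

For each TR codon, the amino acids accessible by adenine mutagenesis
are found by substituting every adenine position independently with
each of A/C/G/T, translating with the standard genetic code, and
dropping stop codons (DGRs that recoded into a stop would truncate their
target, hence "not directly recoding to a stop"). Codons without
adenine are invariant. IUPAC Y/R letters are accepted only when every
resolution yields the identical set — AAY qualifies (AAC and AAT both
give 15 amino acids), while e.g. ARA does not (its resolutions give 20
vs 5) and is rejected with both counts named.

The theoretical diversity $D_{max}$ is the product of per-codon
accessible counts. Products overflow doubles quickly (fifteen 15-way
codons already reach $10^{17}$), so they are computed exactly in a
small base-10⁴ schoolbook multiplier and reported as decimal strings
alongside a numeric value and a 3-significant-digit scientific
rendering.

Observed diversity $D_{obs}$ comes from reads over the VR: at each
variable codon (TR codons containing adenine), every read that fully
and unambiguously covers the codon *and agrees with the TR at the
codon's non-adenine positions* is translated; distinct amino acids with
at least `min_reads_per_variant` supporting reads are collected, and
$D_{obs}$ is the product of per-position counts (uncovered positions
contribute 1 and are flagged). The adenine-consistency filter restricts
observations to codons actually reachable by the DGR mechanism; without
it, sequencing errors at non-adenine positions could push an observed
set outside the accessible set and break the invariant
$D_{obs} \le D_{max}$.

## The synthetic community generator

The generator emulates the study design the analyses were built for:
two sites × two vegetation zones (ALJR, ALSA, MASA, MASP by default,
two samples each, 10⁶-read libraries), i.i.d. genomes at a target GC,
genes covering at least half of each genome, and three layers of planted
variation with a machine-readable truth set:

* **Between-site divergence** — fixed (frequency-1.0) substitutions at
  rate 0.01/bp in the non-reference site, the signature of divergent
  resident populations rather than within-sample polymorphism.
* **Within-site SNVs** — polymorphic sites at 2/kbp with minor fraction
  0.3, shared by the samples of a site.
* **Coverage** — per-position depth Poisson with mean 20× times a
  per-sample abundance multiplier (log-normal, sdlog 0.4, unless fixed
  by the config), and a uniform 0.5% error spread equally over the three
  wrong bases. These are the simplest models under which the callers'
  expected behaviour is derivable in closed form.

Optionally a group-specific deletion (zeroed depth over an interval) and
a DGR cassette are planted. The injected cassette places an RT
placeholder, an intergenic TR, and a target ORF carrying the VR at a
codon boundary. Two construction choices make the truth set exact
rather than approximate: mismatches are spaced at least 5 columns apart
and at least 9 columns from the repeat ends, and the TR's flanking
bases are forced to differ from the VR's flanks, so the planted
alignment is the unique maximal-scoring one and "exact coordinate
recovery" is well defined. Variable codons are exactly the
mismatch-hosting codons, drawn from adenine-rich codons (≥ 13
accessible amino acids), so any requested 2–8 variants-per-position
read simulation is realizable; all other TR codons are adenine-free.
Real TRs also carry conserved adenines outside mismatch columns, which
this construction intentionally omits in exchange for an exact truth
set.

Determinism: every artifact draws from a named RNG substream derived
from the master seed, so regenerating one artifact never perturbs
another, and an identical config reproduces every output file
byte-identically.

What the generator does **not** emulate: read-level artifacts (quality
decay, strand bias, duplicates), assembly and binning error,
strain mixtures beyond a single biallelic minor fraction, indels and
rearrangements beyond clean deletions, and compositional biases of real
sediment communities. Passing the recovery suites therefore shows the
estimators are correct under their stated models, not that those models
capture everything in real recruitment data.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale by choice: 10–50 kb
genomes, 1–4 samples per group, 20 replicate seeds for detection
recall/false-positive rates, 10 seeds for SNV parameter recovery.
Coordinates are 1-based inclusive everywhere in files (BED input is
converted at the I/O boundary); missing values are flagged `NA`, never
silently zero; ties in the SNV major base go to the alphabetically
first base (affecting only the degenerate 50/50 case); and the
pipeline's JSON report contains no timestamps so identical runs are
byte-identical.

## Limitations

Guild classification is only as good as the gene-presence input; GCPM
inherits any coverage-estimation bias of the upstream mapper; the
region detector reports presence/absence patterns, not mechanisms
(deletion vs plasmid vs island); DGR detection requires RT coordinates
and ungapped TR/VR collinearity; and $D_{obs}$ is a lower bound that
grows with sequencing depth, so cross-sample comparisons of realized
diversity must hold mapped reads comparable.
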