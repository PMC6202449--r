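---
title: "Methods: bin curation diagnostics and their synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin curation diagnostics and their synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic generator does
and does not emulate, and the places where the design was genuinely open.

## The setting

Shotgun sequencing of a non-axenic culture yields an assembly containing
one target organism plus its co-cultivated microbiome. Binning partitions
the contigs into per-organism bins using two signals: oligonucleotide
composition (tetranucleotide frequencies, TNF) and sequencing coverage.
The package implements the curation layer around such a workflow: choosing
a binning preset from bin QC statistics, screening bins for foreign
sequence, explaining why rRNA genes tend to be missing from bins, and
comparing bins of unequal completeness.

## Canonical TNF profiles

`tnf_vector()` slides a width-4 window with step 1 and counts each window
under the lexicographic minimum of the 4-mer and its reverse complement:
136 dimensions instead of 256, making profiles strand-agnostic (contigs
have no defined strand). Windows containing `N` are skipped, not
randomized: randomization would inject noise that depends on the RNG
state, whereas skipping merely shrinks the window count, and the count is
carried in the result (`n_windows`). A sequence with no valid window is an
explicit error ("undefined profile"), never a zero vector. Distances
between profiles are Euclidean; no metric is canonical for TNF vectors and
the Euclidean choice keeps the intra-bin distance distribution easy to
reason about.

Bin profiles (`bin_profile()`) use a contig-length-weighted centroid
(renormalized), because a 200 kb contig should dominate a 3 kb one in
describing a bin's composition. The bin depth summary is a length-weighted
*median* (lower weighted median, averaging at exact boundary splits),
robust to the depth outliers this package is specifically hunting.

## The divergence diagnostics

For a contig against a bin profile, two statistics:

- `coverage_ratio` — contig depth over the bin's weighted median depth.
  Scale-free: invariant to uniform depth rescaling of the metagenome.
- `tnf_z` — the contig-to-centroid distance standardized against the
  mean/sd of the bin members' own distances to the centroid. With fewer
  than three members the sd is undefined and the z-score is reported as
  missing, never as 0.

The z-score form was chosen because the source analysis reports composition
divergence only qualitatively; standardizing against the intra-bin
distribution gives a threshold (`z_threshold`, default 2) a portable
meaning across bins of different tightness. The coverage cut-off
(`ratio_threshold`, default 1.5) is likewise this package's
operationalization: a collapsed two-copy operon already doubles coverage,
so 1.5 splits "ordinary fluctuation" from "repeat collapse" with margin on
both sides. Both thresholds are arguments and both raw scores are always
reported, so verdicts are re-derivable under any other convention.

`rrna_fate()` scores each rRNA-bearing contig against its *nearest bin by
TNF centroid* (not by coverage): composition is the more stable assignment
signal for short contigs, and coverage is one of the two quantities under
test. Verdicts: `binned` whenever the binner kept the contig, otherwise
`lost_coverage` / `lost_composition` / `lost_both` / `lost_other` according
to which thresholds are exceeded.

## The reference binner and preset selection

`bin_contigs()` is deliberately *not* a re-implementation of any production
binner. It links contigs when both the TNF distance and the absolute log2
depth ratio fall under the preset thresholds and takes single-linkage
components; contigs under 2.5 kb and components under 50 kb total go to
`nobin`. Preset thresholds (TNF 0.10/0.08/0.06/0.05/0.04; log2 depth
1.5/1.2/1.0/0.8/0.6) tighten strictly from `verysensitive` to
`superspecific`, which yields the testable monotonicity that stricter
presets never assign more contigs. These scales suit the synthetic world
(TNF sampling noise between 2.5 kb fragments of one genome is ≈ 0.03;
between-genome distances run ≈ 0.1); they are configurable for other
worlds.

`select_preset()` compares presets on the largest bin's (contamination,
strain heterogeneity, completeness), minimizing the first two and
maximizing the third; exact ties recurse to the next-largest bin. Two
conventions had to be fixed where the procedure's description is silent:
strain heterogeneity is *minimized* (contamination-like semantics — it
counts marker-gene redundancy among close strains), and a full tie returns
the most sensitive of the tied presets (permissive binning retains more
data; the tie means specificity bought nothing). Missing QC fields rank
worst rather than being imputed. The selection is invariant to the order
the tables are supplied.

`merge_advisory()` recommends merging only for marker-complementary bins
whose taxon labels are both non-root and nested (ancestor-or-equal) in the
packaged lineage map — the conservative reading of "never merge without
congruent placement". `quality_tier()` implements the reduced MIMAG-style
rule: medium at completeness ≥ 90 % and contamination < 5 %, high when a
SSU rRNA gene is additionally affiliated. The full standard also requires
tRNA counts; since no tRNA data flows through this package, the high tier
here over-calls relative to the full standard, and the package makes no
claim to reproduce high-quality counts that depended on it.

## Contamination screen

Bins are split into non-overlapping 250-nt pseudo-reads; the trailing
fragment is discarded by default (uniform read length taken literally; a
`keep_tail` flag exists). Classification is best-hit (max bitscore, tie →
min e-value, tie → input order); an LCA alternative (longest common taxon
path prefix) is available behind `lca = TRUE`, and neither rule is claimed
to replicate any specific external parser. A read is *self* when its taxon
path contains the bin's taxon at or below the comparison rank (default
phylum). The foreign percentage is computed over classified reads only —
no-hit reads carry no evidence either way — and both `n_reads` and
`n_classified` are reported so the other convention is recomputable.

## Completeness-normalized identity

For bins A and B with completeness fractions $c_A, c_B$ and canonical
21-mer sets $K_A, K_B$ (k odd, so no k-mer equals its reverse complement),
raw containment is $|K_A \cap K_B| / \min(|K_A|, |K_B|)$. If A and B are
independent samplings of one genome, the expected containment of the
smaller set equals the completeness of the *other* bin, $c_\mathrm{other}$.
Hence

$$\mathrm{identity} = \min\!\left(1,\;
  \frac{\mathrm{containment}}{c_\mathrm{other}}\right).$$

The measure is symmetric (the containment side and $c_\mathrm{other}$ flip
together), non-increasing in the claimed $c_\mathrm{other}$, near 1 for
same-genome pairs at any completeness, and near 0 for unrelated genomes
(21-mer collisions between random 10^5-10^6-mer sets are negligible).
Completeness values are *inputs* (QC-table percentages / 100), never
re-estimated from the k-mer sets themselves — the normalization assumes an
external, marker-based completeness. This formulation is an
operationalization of "an identity measure comparable across unequal
completeness"; no numeric agreement with any external implementation of
that idea is claimed. The independence assumption fails for bins whose
missing fractions are correlated (e.g. both systematically missing the
same high-GC regions); in that regime the measure overestimates identity.

## Statistics dialect

`quantile_type7()` is the linear-interpolation quantile
$h = (n-1)p + 1$, interpolating between adjacent order statistics. This
dialect decision matters: it is the convention under which the packaged
QC table reproduces its printed medians and IQRs exactly (completeness
median 97.74/IQR 4.04; scaffold 238/292; microbiome scaffold 232/205; the
contamination IQR computes to 0.825, printed as 0.83 under half-up
rounding). One printed pair — the microbiome completeness median/IQR —
does not recompute from the packaged table under this (or any standard)
quantile dialect; the underlying bin subset evidently differed from the
printed table. The package records this as a known discrepancy and asserts
nothing about it. `pearson()` reports the sample correlation with the
two-sided t-transform p-value.

## The synthetic world

`simulate_genome()` draws each genome from its own Markov chain (order
0-2, default 1) whose transition rows are Dirichlet(1) samples under a
per-genome `composition_seed` — so composition is a property of the genome
spec, reproducible across runs, and distinct seeds give distinguishable
TNF profiles. `fragment_and_cover()` cuts the genome at random breakpoints
into contigs with lengths uniform in a configurable range, and assigns
depths from a truncated Normal with 5 % CV around the genome's coverage (a
noise model chosen as typical of within-genome depth variation at MiSeq
scale; nothing in the source material fixes one).

rRNA operons are drawn from a separate genome-independent chain (order 1,
sharpened so operon composition diverges from any Dirichlet background;
one draw per genome from that common chain) —
mirroring the fact that rRNA composition diverges from genomic background.
With ≥ 2 copies, all copies collapse into ONE contig of operon length
whose depth is coverage × copies; the collapsed contig carries 10 %
genome-background flank on each side, as a real assembler leaves around a
collapsed repeat. The flanks matter: they anchor the contig's nearest-bin
(by TNF) to its genome of origin while leaving the composition strongly
divergent, exactly the configuration in which the fate diagnostics are
meaningful. A single copy is instead inserted in place into an ordinary
contig. Length bookkeeping is exact: emitted sequence equals genome length
minus (copies − 1) operon lengths.

The packaged `demo_community()` is the stated world for end-to-end checks:
two 200 kb genomes, coverages 10× and 40×, four operon copies each,
2.5-15 kb contigs (MiSeq-scale fragment sizes, enough contigs per bin for
stable intra-bin statistics). In this world the binner recovers both
genomes essentially perfectly, and both collapsed operon contigs are
rejected under all five presets with coverage ratio ≈ 4 and z ≫ 3 — the
qualitative mechanism, reproduced deterministically.

What the generator does *not* emulate: read-level errors, chimeric
contigs, strain microheterogeneity, inter-genome homology (synthetic
genomes share no sequence except the operon), GC-coverage bias, or
multi-sample coverage profiles. A green end-to-end test therefore
establishes that the implementation expresses the stated mechanism, not
that the binner or the diagnostics would perform identically on real
assemblies.

## Parameter-recovery properties

The identity measure is validated by simulation: one 300 kb genome cut
into 1-2.5 kb contigs, independent contig subsamples at fractions
{0.3, 0.5, 0.7, 0.9}² (five seeds), claimed completeness set to the
realized fractions. The panel's mean normalized identity exceeds 0.95 and
mean raw containment tracks c_other within 0.05; unrelated genomes score
< 0.02. The 1-2.5 kb granularity is a design choice: contig-level
subsampling noise scales as the inverse square root of the contig count,
and coarser fragmentations make single (0.3, 0.3) cells noisy without
changing the expectation.

## Known limitations

- The binner is a qualitative stand-in; its presets are not calibrated to
  any production tool's output on real data.
- The affiliation operation is mechanical taxon-congruence matching; the
  packaged rRNA table carries curated affiliations as *data*, and counts
  derived from it are fixture counts, not re-derivations of the curation.
- The lineage map covers the taxa appearing in the packaged tables plus
  common neighbors; unknown labels never affiliate and are counted under
  an explicit "other" category with a warning.
- `foreign_pct` depends on the completeness and bias of the external hit
  database; the package only implements the parser arithmetic.
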