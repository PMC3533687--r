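---
title: "Modelling DNA methylation reprogramming in primordial germ cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA methylation reprogramming in primordial germ cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcmeth)
```

## Scope and model

Mouse primordial germ cells (PGCs) erase most genomic DNA methylation in
two phases: a global, passive loss during expansion and migration
(complete well before E9.5 for the bulk of the genome), and a later,
targeted erasure of sequences carrying long-term epigenetic memory —
imprinted germline DMRs, X-linked CpG islands, and CGI promoters of
germline-specific genes — once PGCs enter the gonads. IAP
retrotransposons resist erasure throughout, as do sequences in their
neighbourhood, and a set of variably erased CGIs (VECs) retains
methylation in a sex-biased way. `pgcmeth` turns this picture into a
testable pipeline: a seeded simulator of annotations, bisulfite call
tables, hairpin reads and expression time courses, plus the
quantification, classification, and model-fitting layers that consume
them.

The package operates entirely on synthetic data. The developmental
stage roster is E6.5 epiblast, E9.5/E10.5/E11.5 migrating PGCs, and
sexed E13.5 and E16.5 germ cell samples.

## The methylome generator

Each CpG dyad belongs to a feature class (or to the bulk genome), and
its *true* methylated fraction follows a deterministic trajectory
(`expected_class_level()`):

* **Passive dilution.** Unprotected sequence halves its methylated
  fraction at every cell division: after $d$ cumulative divisions the
  level is $m_0 \cdot 2^{-d}$. The bulk initial level is 0.71 (the
  epiblast value), ordinary CGIs and CGI promoters start at 0.15
  (CGIs are mostly unmethylated in soma).
* **Protection and late erasure.** DMR cores (0.5: one methylated
  parental allele), germline-gene promoter CGIs (0.8: methylated in
  soma) and X-linked CGIs hold their level through E11.5 and drop to 0
  at the erasure stage (default E13.5, gonadal entry). Configuring
  erasure before the end of the protection window is rejected.
* **X-linked CGIs and sex.** In cells with random X inactivation the
  inactive-X CGI copy is methylated: female-lineage level 0.5, male 0,
  and 0.25 in a 50/50 mixed pool (each simulated cell's sex is drawn
  50/50 and contributes one sampled allele per read). This reproduces
  the elevated E6.5 epiblast signal of a mixed-sex pool qualitatively.
* **Resistance.** IAPs hold 0.9 at all stages. A CpG-poor promoter at
  edge-to-edge distance $d$ bp from an IAP is held at
  $0.9\,e^{-d/1500}$ when that exceeds its passive level; this decay
  crosses the 25% resistance threshold near 2 kb, which is why the
  2 kb proximity cutoff separates consistently resistant from variable
  features. VECs hold a per-feature residual drawn from U(0.05, 0.65)
  in the male germline, scaled by 0.6 in the female germline
  (male-biased escape from erasure).
* **De novo gain.** Only E16.5 male samples gain methylation, toward a
  target of 0.5, at de novo-eligible classes (bulk, gene bodies,
  LINE1s, CpG-poor promoters). No gain occurs at any stage E6.5–E13.5,
  making erasure unidirectional.

Observed counts are drawn per strand with Poisson coverage at the
sample mean (simple, and dispersed enough for shallow BS-Seq) and
binomial methylated counts at the apparent fraction
$m + (1 - m)\varepsilon$, where $\varepsilon$ is the bisulfite
conversion-failure rate (default 0.002). CHH sites are truly
unmethylated, so apparent CHH methylation estimates $\varepsilon$; with
roughly 200 CHH observations per 1 kb probe the expected fraction of
fully converted probes is $(1-\varepsilon)^{200} \approx e^{-0.4}
\approx 0.67$, comfortably above the 60% quality bar the analysis
expects.

**Divisions per stage interval** are configurable (default 2 per
interval E6.5→E9.5→E10.5→E11.5→E13.5, none to E16.5 when germ cells
arrest); no published cell-cycle counts exist for these intervals, so
the default is a modelling choice, not an estimate. Under it the bulk
trajectory runs 71% → 17.8% → 4.4% → 1.1% → 0.28%; the published
genome-wide percentages derive from real sequencing data and are not
targets of the simulation.

## Quantification

Tiling probes (default 5 kb; 1 kb for conversion control) partition
each chromosome, keeping the last partial window. Within a probe or
feature, methylation is the read-count **weighted** percentage
$100\sum m / \sum(m+u)$; across probes, the global figure is the
unweighted mean of probe percentages (a median variant is exposed).
Both strand calls of a dyad count toward the interval containing the
dyad position (the top-strand C). Cells with fewer than 10 informative
counts (20 CHH observations for conversion probes) are *missing*,
never zero. A probe counts as fully converted only if its methylated
CHH count is exactly zero — a literal criterion, not a rounded
percentage. The density–methylation association uses the Pearson
correlation between per-probe covered-CpG counts and percentages.

## Classification rules

All classification operates on per-stage replicate **medians**.
Thresholds are strict: a late demethylater must exceed 25% at *every*
stage E6.5–E11.5; a resistant feature must exceed 25% at its sexed
E13.5 value; IAP proximity is a strict `< 2000` bp edge-to-edge
distance. Features missing at any rule stage are excluded from
selection and reported separately rather than silently failed. VECs
are features resistant in at least one sex and *not* IAP-proximal;
because no quantitative definition of "variable" erasure exists, the
package reports a continuous per-feature methylation range and a
sex-bias sign instead of thresholding variability. Enrichment of a
selected set for site-bearing features (e.g. Zfp57 motifs) uses the
ratio of hit fractions with a hypergeometric upper-tail probability.

In mixed-sex pools, protected X-linked CGIs sit at an expected 25% —
exactly at the strict threshold — so recovery of X-CGIs by the 25%
rule is assessed on a female-lineage roster
(`default_stage_specs(sex_mode = "female")`), where their expected
level is 50%.

## Hairpin analysis and the dilution model

Hairpin bisulfite reads report both strands of each CpG dyad: states
`M` (both methylated), `T`/`B` (hemimethylated, top/bottom), `U`, and
`.` (missing; dropped, never imputed). The strand joint distribution
tallies per read the number of `T` and `B` dyads; under **passive**
demethylation every hemimethylated meC sits on the molecule's single
template strand, so all mass lies on the axes, while **active**
(strand-agnostic) removal scatters meCs binomially across strands. The
default amplicon has five dyads. Observed joints are compared to the
two simulated nulls by total-variation distance — the published
comparison is visual, so a symmetric, bounded distance is the natural
formalization — and the verdict is the nearer null, with ties reported
as indeterminate. Reads with no hemimethylated dyads land in cell
(0,0) and are excluded from the confined-fraction denominator.

The dilution model tracks the population distribution over dyad states
(M, H, U), pooling hemimethylation over strands (strand detail lives
in the hairpin layer). Per division, replication/maintenance acts
first — a methylated template's partner is restored with maintenance
efficiency $p_m$, unmethylated copies gain de novo methylation at
$p_d$ — and active removal then strips each methylated cytosine
independently at $p_a$; the expectation over both daughters gives a
linear (3×3 stochastic) update. The event order is a modelling choice;
nothing in the data constrains it. With all rates zero the methylated
fraction $f_M + f_H/2$ halves exactly per division.

`fit_dilution()` maximizes the multinomial likelihood of observed
(M, H, U) counts under trajectories started from the first timepoint's
empirical distribution. The likelihood can be sharply peaked in $p_m$
at realistic counts, so the search runs a coarse grid (step 0.05) and
then box-constrained local refinement multi-started from the best
(p_d, p_a) of each leading $p_m$ slice; this replaces a finer global
grid at a fraction of the cost and recovers $p_m$ within ±0.05 from
10⁴ dyads over four timepoints. At high maintenance ($p_m \to 1$) an
active-removal component can partially mimic maintenance failure, so
joint ($p_m$, $p_a$) estimates trade off there; the profile-likelihood
slice along $p_m$ is returned to make this visible.

## Expression layer

The expression generator plants a pluripotency-like cluster (peaking
at E11.5, declining steeply to E16.5) and a meiosis-like cluster
(rising from E13.5, highest in female E13.5/E16.5) on a log2 scale
over 8 stage samples, on top of a large uncorrelated background
(default 1940 genes, a fraction fully silent) whose band occupancy is
constant across samples. Clustering standardizes per-gene log2
profiles, applies average-linkage hierarchical clustering on
correlation distance, cuts at a similarity threshold (default 0.7,
exposed because the published similarity definition is not available),
and discards clusters below a minimum size; output is deterministic
under gene reordering. The published cluster count is treated as
data-dependent, not a contract. Expression complexity uses three broad
bands (edges 4 and 64 on the expression scale) plus a silent band.
Repeat expression consumes pre-tallied per-target read counts — no
alignment is performed — with a LINE1 burst planted exclusively in
female E16.5. The methylation–expression association uses Spearman
correlation (robust to the heavy right tail); because the annotation
generator does not model genes-with-bodies, the expression generator
itself emits an E16.5-male gene-body methylation vector positively
coupled to that sample's expression for demonstration and testing.

## What the simulation does and does not show

The generator reproduces the *structure* the analysis assumes —
two-phase kinetics, protected classes, finite coverage, conversion
failure, strand-confined hemimethylation, planted expression dynamics
— with class-homogeneous levels and independent sites. It does not
model site-to-site rate heterogeneity, linkage between neighbouring
CpGs, 5hmC intermediates, PCR duplicates or mapping artefacts, or real
genome coordinates. Passing tests therefore certify the correctness of
the quantification, selection and model-fitting machinery under the
stated assumptions, not the biological conclusions on real data.

## Problem sizes and numerics

Default demonstration scale is a 10 Mb three-chromosome genome
(~190,000 CpG dyads, 200,000 CHH sites) with 8–16 samples at 10–50×
coverage, chosen so the full pipeline runs in well under ten minutes
on one CPU; unit tests use a 1.9 Mb genome. Percentages are computed
in double precision with no rounding; missing is `NA` throughout and
never conflated with 0; selection ties at thresholds resolve by the
strict inequalities above; cluster ids order by size then lowest
member id; all randomness flows from explicit integer seeds, and
equal seeds give byte-identical outputs (the pipeline manifest hashes
every file to make this checkable).
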