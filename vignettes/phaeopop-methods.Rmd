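---
title: "phaeopop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phaeopop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaeopop)
```

This vignette is the package's own account of its science: the statistics
it implements, the synthetic world its simulator states, why each default
is what it is, and what a green test does and does not establish. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The conservation statistic

For one gene, the protein products of all isolates are stacked into an
alignment of `L` columns. Column `i` gets the Shannon entropy

$$H_i = -\sum_a p_a \log_2 p_a,$$

where `a` runs over the residues observed in that column and `p_a` is the
count of residue `a` divided by the number of informative residues. The
gene's conservation score is the length-standardized sum
$(\sum_i H_i)/L$: zero for a perfectly conserved gene, increasing with
segregating protein variation. The score is invariant to row order and to
duplicating the whole row set, so it measures diversity, not sample size
bookkeeping.

Numerical and edge-case choices:

* **Log base.** Bits (base 2) by default, natural log available; every
  profile records its base. The fully conserved case — score exactly 0 —
  is base-invariant, which is why a fully constrained housekeeping gene
  (*recA* in the default roster) is the anchor the tests pin down.
* **Gaps and `X`** are excluded from the column denominator; a column
  with no informative residue contributes 0 but still counts in `L`. The
  synthetic data are gap-free, so this choice only matters for user-supplied
  pre-aligned proteins, and it is the least-assuming one.
* **Stop codons.** Translation uses the bacterial genetic code (table 11)
  with the alternative-initiation rule for the first codon. A single
  terminal stop is trimmed — but in a gene *set* only when every record
  ends with one, so a mutation that creates a stop in the last codon of
  one isolate remains visible. Internal stops are kept as `*`, a 21st
  symbol: pseudogenization inflates entropy instead of vanishing.
* **Alignment is upstream.** Equal-length inputs are stacked directly;
  unequal-length inputs must arrive pre-aligned. The package bundles no
  aligner: the statistic is defined on columns, and which aligner
  produced them is the caller's methodological choice.

### The group test

The question "do biosynthetic genes carry more diversity than
housekeeping genes?" is answered with a Welch t-test (Student optional)
*and* an exact permutation test of the mean score difference. With 6
target genes (*tdaA–F*) against 3 references (*gyrA*, *rpoB*, *recA*)
there are only C(9,3) = 84 relabelings, so a permutation p-value can
never be smaller than 1/84 ≈ 0.012 — reporting that floor explicitly is
more honest at these group sizes than a t approximation alone. When both
groups have zero variance and equal means the t-statistic is undefined;
the package returns p = 1 with a `degenerate` flag rather than NaN.
Whether the two roseobacticide-associated genes (sulfurase, glutathione
S-transferase) belong in the target group is genuinely open; the default
tests *tdaA–F* only and `default_gene_groups(include_roseobacticide =
TRUE)` pools them.

## 2. Clade structure

Synthetic "ANI" is the exact fraction of identical positions between
equal-length concatenated gene sets; real-genome ANI matrices (from
MUMmer/BLAST-based tools) are ingested from labeled square TSV/CSV, with
the percent-vs-fraction dialect auto-detected and asymmetry beyond 1e-6
rejected. Clades are flat clusters of average-linkage hierarchical
clustering on `1 − identity`, cut at `1 − cut_identity`, numbered by
first appearance in input order, and exportable as a Newick dendrogram
whose branch lengths are merge distances.

The study this package emulates never states its linkage or cut height,
so there is no silent default cut for real data: `cluster_clades()`
requires an explicit `cut_identity`. On synthetic data the tests derive
the cut from truth — midway between the within-clade and between-clade
identity supports — and require exact recovery (adjusted Rand index 1),
which holds for *any* cut strictly between the supports. Tie-breaking
inside the clustering relies on `stats::hclust`'s deterministic merge
order; exact ties do not occur on real-valued synthetic identities, and
input-order invariance is property-tested up to renumbering.

## 3. Censored abundance statistics

Plate counts below the limit of detection (LOD, 1 Log10 CFU per ml or g)
are left-censored: the observation is "< LOD", not a number. The package
keeps an explicit censored flag on every value, carries the LOD as the
numeric stand-in, and never drops censored replicates silently.

* **Summaries** report mean ± s.d. over *detected* replicates (the
  field's reporting convention) alongside LOD-substituted variants; a
  time point with all replicates censored prints "&lt;LOD".
* **Rank tests.** Kruskal–Wallis H (with the standard tie correction)
  followed by Dunn's pairwise z, Bonferroni-adjusted over all pairs.
  Censored observations enter as ties at the LOD: a rank test only needs
  ordering, and any sub-LOD value is exchangeable — a property the suite
  asserts directly by substituting arbitrary sub-LOD values.
* **Bimodality.** Time-point means are classified below-LOD /
  intermediate / high (within `high_margin = 1` log of the series
  maximum). The series is flagged bimodal when both extreme states are
  occupied and at most 20% of time points are intermediate. A flat
  series occupies only the high state and is not bimodal.
* **Peak lag** compares argmax positions of time-point means on shared
  sampling points, ties toward the earliest peak, positive = host leads.
  No smoothing: with monthly-at-best sampling, smoothing would
  manufacture precision the data do not have.

## 4. The synthetic world

The simulator states one explicit world and the tests interrogate it.

**Genetic layer.** A clonal population descends from `C = 8` founder
genotypes, each `d = 106` substitutions from a common reference.
Generations are discrete Wright–Fisher multinomial resampling; each
offspring receives Poisson(μ × U) mutations placed uniformly on the U
unconstrained sites with a uniform choice among the three alternative
bases. Purifying selection is modeled as *site immutability* — a fixed
fraction f of each gene's sites never mutates — because the claim being
emulated is conservation, not a dN/dS estimate, and immutability gives a
clean, monotone truth parameter. No recombination, indels, codon bias or
spatial structure; sequences therefore never need alignment. The
reference is drawn from sense codons only, so stop codons arise only by
mutation (pseudogenization), as in real data.

**Founder placement.** Each founder's d substitutions are apportioned
across genes *proportionally to unconstrained length* (largest-remainder
rounding), uniformly within a gene. The per-gene founder divergence
density is then representative of `1 − f` instead of carrying a second
layer of sampling noise; placement of the ongoing mutation process stays
fully uniform.

**Demography.** The abundance schedule (two seasons per year, twelve
years: summer peaks of 5.2 Log10 CFU g⁻¹, winter troughs below the 1
Log10 LOD) is an observation layer. Drift acts on a *scaled* effective
population: geometric interpolation between `effective_size_cap = 2000`
at schedule peaks and `trough_effective_size = 128` at troughs, hard-floored
at C. Simulating the literal 10⁵-cell census would drown drift and the
literal trough (a handful of cells) would coalesce all clades within a
few winters — contradicting the decade-long clade persistence the
emulated system actually shows — so the scaled pair (2000, 128) is the
stated compromise: a 16-fold seasonal crash that produces uneven,
drifting clade frequencies while typically retaining most founder
lineages across a decade. By default each surviving clade is guaranteed
at least one descendant per generation (the drift floor);
`allow_extinction = TRUE` lifts that guard for studying clade loss.

**Sampling.** Isolates are drawn uniformly without replacement at
scheduled time points; default event sizes mirror the emulated study's
per-event sequenced counts (4–21 isolates, 11 events, 114 total).
Requesting more isolates than the census at a time point is an error
naming the time point.

**Calibration of d.** The only external anchor for between-clade
divergence is the species-level minimum ANI of 0.986. With U ≈ 2421
unconstrained sites over the 14,487-nt genome, `d = 106` makes the
founder-only (μ = 0) minimum pairwise identity ≈ 1 − 2d(1 − d/U)/L ≈
0.986. Mutation load (μ = 1e-4 over ~190 generations) adds ~40–60
differences to the oldest pairs, so realized minima in sampled runs are
~0.979–0.981 — the founder geometry, not the realized minimum, carries
the calibration.

**Constraint ladder.** The default constrained fractions are

| gene | f | | gene | f |
|---|---|---|---|---|
| recA | 1.000 | | tdaC | 0.79 |
| rpoB | 0.996 | | tdaE | 0.71 |
| gyrA | 0.987 | | tdaA | 0.62 |
| sulfurase | 0.965 | | tdaD | 0.48 |
| gst | 0.905 | | tdaF | 0.30 |
| | | | tdaB | 0.03 |

These are *identifiability-driven truth parameters, not biological
estimates*. The ANI ceiling fixes the total founder divergence budget at
roughly 200 sites, so conserved genes receive only a handful of variant
columns and adjacent entropy ranks flip unless expected scores of
neighboring genes are separated by about three standard deviations of
their log-score difference. The ladder above spends the available range
(f from 1 down to 0.03) to satisfy exactly that budget, while preserving
every ordering the emulated biology pins down: *recA* exactly zero;
housekeeping well below the biosynthetic cluster; *tdaC* the most and
*tdaB* the least conserved TDA gene; the two roseobacticide-associated
genes highly constrained; *tdaB* doubling as the near-free gene that
anchors the fast end. The design was fixed from pilot runs before the
acceptance tests were written, and a 30-seed pilot recovered the full
rank order in 30/30 runs at the chosen parameters.

**What a green test establishes — and what it does not.** Rank recovery
and test power on this world show the *pipeline* is correct and
adequately powered for effects of the designed size; they do not
estimate the real genes' constraint, the real clades' ages, or the real
population's effective size. Features of real data the generator does
not emulate: recombination and gene flow, indels and annotation error,
uneven sequencing quality, within-host structure, and any fitness
differences between clades.

## 5. Fixtures and the inventory table

The packaged sampling-inventory fixture reproduces the emulated study's
printed 20-event table, including its "Total" row (121 isolates
obtained, 112 sequenced) and `ND` missing-value convention. The parser
treats the printed totals as authoritative and separately reports the
row-wise sums; for the sequenced column those sums give 114, a
2-isolate discrepancy internal to the printed table that the package
surfaces with a message instead of silently reconciling. Dates are
opaque ordered labels — the data's resolution is month-year, and two
samplings eleven days apart appear as one label with distinct ordinals —
so no calendar arithmetic is attempted beyond ordering.

## 6. Reproducibility mechanics

Every stochastic entry point takes a seed and restores the caller's RNG
state afterwards. The CLI logs version, seed and the effective config to
stderr and writes results only to files; identical config + seed yields
byte-identical reports, which the suite asserts. Configs are JSON or a
small YAML subset parsed in-package (nested maps, scalars, inline and
block lists) — sufficient for the documented schema without adding a
YAML dependency the installation image does not carry.

## 7. Known limitations

* The entropy ranks of *very* conserved genes are inherently noisy at
  realistic divergence; the simulator's constraint ladder is spread to
  keep them identifiable, which trades biological realism of the f
  values for statistical power (documented above).
* Sample-level clade persistence (a clade present in *every* seasonal
  sample) is a property of individual realizations, as it was of the
  single observed history being emulated; the drift floor guarantees
  persistence only at the population level.
* Exact permutation tests are limited to 200,000 relabelings; beyond
  that the package switches to seeded Monte-Carlo (with the observed
  labeling counted, so p ≥ 1/(B+1)).
* The Kruskal–Wallis p-value uses the chi-square approximation; at very
  small group sizes an exact network algorithm would be preferable but
  is out of scope.
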