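# phaeopop

Population-level analyses for a host-associated, seasonally oscillating
*Phaeobacter* population, reconstructed from cultured isolates sampled over
many years.

Marine *Phaeobacter* spp. produce the antibacterial compound tropodithietic
acid (TDA) and live in association with eukaryotic hosts such as bryozoans.
A long-term isolate collection from one harbor raises three recurring
questions that this package answers with tested, reusable code:

1. **Are the biosynthetic genes conserved?** For each gene, the protein
   products of all isolates are stacked into an alignment and the Shannon
   entropy of every amino-acid position is computed,
   H_i = −Σ_a p_a log₂ p_a. The per-gene conservation score is the
   length-standardized sum (Σ_i H_i)/L — 0 for a perfectly conserved gene.
   TDA-cluster scores (*tdaA–F*) are tested against housekeeping baselines
   (*gyrA*, *rpoB*, *recA*) with a Welch t-test and an exact permutation
   test (group sizes of 6 vs 3 make the permutation test the honest
   choice: its p-value can never undercut 1/84).
2. **Is it one species, and how is it structured?** Pairwise identity /
   ANI matrices (computed exactly on synthetic data, or ingested from
   external ANI tools for real genomes) are checked against the 95%
   species threshold and clustered (average linkage on 1 − identity) into
   clades whose relative abundance is tracked over sampling seasons.
3. **How does abundance behave around the detection limit?** Log10 CFU
   series with left-censoring at the LOD get censoring-aware summaries
   (mean ± s.d. over detected replicates), Kruskal–Wallis tests with
   Dunn's post hoc and Bonferroni correction (censored values enter as
   ties at the LOD), a bimodality/occupancy classification, and a signed
   host-vs-seawater peak-lag estimate.

Because the real genomes require downloading and assembling deposited
reads, the package ships a forward-time **simulator** of a clonal,
seasonally bottlenecked population — founder clades, per-gene purifying
constraint (modeled as immutable sites), multinomial drift on a scaled
effective population, Poisson mutation — that generates isolate gene
sets, metadata and censored abundance series with known truth, so every
downstream statistic is testable end to end.

## Worked example

```r
library(phaeopop)

cfg <- simulation_config(seed = 1)     # 8 clades, 11 genes, 12 years
sim <- simulate_population(cfg)        # 114 isolates across 11 summers
rep <- conservation_report(isolate_gene_sets(sim$isolates),
                           default_gene_groups(), type = "cds")
rep$table
#>         gene     group n_sequences    L   score
#> 1       tdaA    target         114  350 0.17476
#> 2       tdaB    target         114  148 0.41972
#> 3       tdaC    target         114  251 0.10022
#> ...
#> 8       recA reference         114  347 0.00000
#> 9       rpoB reference         114 1380 0.00207
rep$comparison
#> group comparison (permutation_exact, alternative = greater)
#>   n = 6 vs 3; mean diff = 0.219
#>   t = 4.324 (df = 5), two-sided p = 0.007527, one-sided p = 0.003763
#>   permutation p (greater) = 0.0119 [exact, n = 84]
```

The score column orders genes exactly as their simulated constraint
fractions predict (*recA*, fully constrained, scores exactly 0; *tdaB*,
nearly free, scores highest), and the one-sided exact permutation test
rejects at its combinatorial floor 1/84 ≈ 0.012: the biosynthetic cluster
carries significantly more diversity than the housekeeping baseline —
i.e. on real data the same machinery demonstrates the *conservation* of
the TDA genes relative to how fast an unconstrained gene would drift.

```r
concat <- setNames(vapply(sim$isolates,
                          function(x) paste(x$sequences, collapse = ""), ""),
                   vapply(sim$isolates, `[[`, "", "isolate_id"))
species_check(pairwise_identity(concat))
#> $min_identity    0.9802582
#> $single_species  TRUE          # all isolates above the 95% threshold

occ <- occupancy_bimodality(generate_abundance(cfg))
#> fraction below LOD: 0.5   high: 0.5   bimodal: TRUE
```

Half the seasonal time points sit below the 1 Log10 detection limit and
half within one log of the 5.2 Log10 peak, with nothing in between — the
bimodal oscillation the abundance module is built to characterize.

## Command line

```sh
Rscript -e 'phaeopop::run_cli()' report --config inst/extdata/demo_config.yaml --out out/
```

Subcommands `simulate`, `entropy`, `clades`, `abundance` run the stages
individually; `report` chains them and writes one `report.json` plus
per-stage TSV/CSV/Newick artifacts. Identical config + seed gives
byte-identical reports. Exit codes: 0 success, 1 data error, 2 usage
error.

## What is deliberately out of scope

Genome assembly, external ANI computation (ANIm/ANIb matrices are
*ingested*, not computed), 16S amplicon processing, ordination,
metabolomics and qPCR quantification. See the methods vignette
(`vignettes/phaeopop-methods.Rmd`) for the model, parameter rationale and
limitations.
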