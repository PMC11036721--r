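# trajectomics

Trajectory-pattern analysis of multi-class time-course transcriptomes.

## The problem

Developmental studies often profile a tissue as a bulk transcriptome at many
consecutive ages, pooling individuals into **one library per timepoint** to
suppress batch and individual variation — for example, mouse testis across
nine postnatal weeks, with mRNA, lncRNA, circRNA and miRNA classes profiled
in parallel. That design raises questions that standard replicate-based
differential-expression stacks do not answer directly:

* How do you call differential expression between adjacent timepoints with a
  **single count per condition**? Here: a negative-binomial exact test that
  conditions on the normalized sum of the two libraries, with dispersion
  estimated "blind" across the whole series (method-of-moments per gene plus
  a robust parametric trend α(μ) = a₀/μ + a₁). A gene is a DEG when
  |log2FC| > 1 and p < 0.05.
* How do you summarize a gene's whole trajectory? Each gene becomes a string
  over **U** (up), **D** (down), **M** (maintained), one letter per adjacent
  interval — k intervals give 3^k possible patterns (6,561 for nine
  timepoints). The package builds ranked pattern-frequency tables and
  pattern-space coverage statistics (observed / 3^k).
* Which genes organize the response? A confidence-filtered interaction graph
  (combined score ≥ 0.400) is mined for dense modules (MCODE-style k-core
  seed-and-expand), and hubs are chosen by **consensus over twelve
  centrality measures** (MCC, DMNC, MNC, Degree, EPC, BottleNeck,
  EcCentricity, Closeness, Radiality, Betweenness, Stress, Clustering
  Coefficient — every formula is in `?centrality`).
* Which non-coding RNAs could act as miRNA sponges? Differential
  lncRNA/circRNA and mRNA are joined through **shared differential miRNAs**
  into ceRNA triples and quadruples, with node/edge statistics.

A synthetic-data module generates all inputs with planted ground truth
(NB counts with planted U/D/M trajectories, planted-partition graphs,
planted shared-miRNA triples), so the whole pipeline is testable end to end.
`ora()` adds hypergeometric over-representation against user-supplied GMT
gene sets.

## Worked example

```r
library(trajectomics)

# three named genes with planted trajectories in a background of stable genes
pats <- c(Prm1 = "UMMMMMMM", Sycp3 = "MMMUMMMM", Ddx4 = "MMMMMMMM")
pats <- c(pats, setNames(rep("MMMMMMMM", 37), sprintf("gene%02d", 1:37)))
cfg <- sim_config(pattern_assignments = pats, dispersion = 0.01, fold_step = 8,
                  baseline_log_mean = log(500), baseline_log_sd = 0.3, seed = 42)
sim <- simulate_counts(cfg)
sim$counts
#> CountMatrix: 40 mRNA genes x 9 samples (3w, 4w, 5w, 6w, 7w, 8w, 9w, 10w, 11w)

recs <- de_adjacent(sim$counts)       # size factors + blind dispersion + NB test
subset(recs, status != "M")
#>      gene interval   log2fc      p_value status
#> 1    Prm1    3w-4w 2.869540 8.458118e-32      U
#> 122 Sycp3    6w-7w 2.379711 1.524525e-22      U

traj <- encode_trajectories(recs)
head(pattern_frequency(traj), 3)
#>   rank  pattern count percentage
#> 1    1 MMMMMMMM    38       95.0
#> 2    2 MMMUMMMM     1        2.5
#> 3    3 UMMMMMMM     1        2.5

pattern_space_coverage(traj)
#> $n_unique
#> [1] 3
#> $space_size
#> [1] 6561
#> $coverage_pct
#> [1] 0.05
```

The two planted non-stationary genes are recovered in the right interval and
direction (`Prm1` rises 8-fold entering week 4, `Sycp3` entering week 7), the
frequency table ranks the stable all-M pattern first at 95.0%, and the 3
observed patterns cover 0.05% of the 6,561 possible 8-interval strings.

For networks: `build_graph()` → `extract_modules()` → `preliminary_hubs()` /
`all_centralities()` + `consensus_hubs()`; for ceRNA:
`filter_differential()` → `join_triples()` → `cerna_network()` →
`network_stats()`. See the vignette in `vignettes/trajectory-dynamics.Rmd`
for the statistical background and every numerical convention.

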