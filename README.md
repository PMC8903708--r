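# circflow

Circular RNAs (circRNAs) are covalently closed transcripts formed by
back-splicing; in multiple myeloma, a circRNA of the HNRNPU gene (exons
2–13) is abundant in the IgD subtype, encodes a novel 603-amino-acid protein
through an internal ribosome entry site (IRES), and stratifies patient
survival. `circflow` re-implements the dry-lab discovery pipeline behind
that kind of study as a tested, reusable R package for transcriptomics
researchers: every stage runs on seeded synthetic data that emulates the
statistical structure of the original cohorts, so the full analysis is
reproducible on a laptop with no downloads.

The stages, and the models behind them:

- **Differential screening** — abundance filter (FPKM > 1 in ≥ 3 samples),
  per-probe Welch t-tests on log2 expression, BH correction, and the
  `p < 0.05`, fold-change `> 2` up/down classification; plus the qPCR
  `2^(-ΔΔCt)` utility.
- **Co-expression network (from scratch)** — unsigned weighted adjacency
  `a_ij = |cor(x_i, x_j)|^β`, scale-free soft-threshold scan, topological
  overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  average-linkage module detection with size-ranked colour names, module
  eigengenes (first principal component) and eigengene–trait association.
- **Hub screening** — deterministic multi-class ReliefF feature weighting
  within trait-associated modules, a top-25 hub panel, and unsupervised
  sample clustering on `1 − cor` scored by the adjusted Rand index.
- **Circular ORF prediction** — every AUG on the circle is read across the
  back-splice junction, including rolling-circle ORFs whose coding span
  exceeds the circle length; IRES-proximal starts are annotated,
  junction-spanning probe sequences extracted, and junction-unique tryptic
  peptides derived for MS validation.
- **Alternative splicing** — event classification (SE/A5SS/A3SS/RI/MXE) from
  transcript exon models, effective-length-normalized PSI
  `(I/l_I) / (I/l_I + S/l_S)`, pooled-count Fisher tests with BH correction,
  category summaries and RIP-bound-transcript intersection.
- **Survival and enrichment** — median-split expression dichotomization,
  Kaplan–Meier product-limit curves, two-group log-rank tests, and
  hypergeometric over-representation analysis of gene sets.

Seeded generators (`sim_expression()`, `sim_circle()`, `sim_as_counts()`,
`sim_survival()`, `sim_genesets()`) produce every input with planted ground
truth: a 3/5/5 NPC/IgD/IgG cohort with seven co-expression modules (two
IgD-upregulated), a 1733-nt circle with an IRES at +201–374 and a planted
603-aa rolling-circle ORF, binomial junction counts around true PSI, and
expression-linked exponential survival.

## Worked example

```r
library(circflow)

report <- run_pipeline(pipeline_config(seed = 1))
report
#> <pipeline_report>
#>   probes after filter : 600
#>   DE up / down        : 45 / 22
#>   modules (power 6)  : 7, trait-up: turquoise, green
#>   hub panel           : 25 probes, clustering ARI 1.000
#>   primary ORF         : 603 aa (1 junction crossing(s))
#>   significant AS      : 144 (SE:87 A5SS:18 RI:16 A3SS:15 MXE:8)
#>   log-rank p          : 2.57e-06
#>   top enriched set    : set_planted
```

Reading the report: the simulated 52-sample cohort passes the abundance
filter intact; the IgD-vs-IgG contrast calls 45 probes up and 22 down at the
`p < 0.05`, FC > 2 thresholds; network analysis at soft power 6 recovers
exactly the seven planted modules and flags the two IgD-upregulated ones
(named turquoise and green by module size); ReliefF reduces their members to
a 25-probe panel that reproduces the three diagnostic groups perfectly
(ARI 1.0); the packaged circle yields the 603-aa junction-spanning product;
the splicing stage calls 144 significant events dominated by exon skipping;
high expression carries a significantly worse survival (log-rank
p ≈ 2.6e-06); and the planted gene set ranks first in the enrichment.

Single stages compose with the pipe:

```r
circ <- circhnrnpu_circle(seed = 1)
find_circular_orfs(circ) |> annotate_ires(circ) |> primary_orf()
#> # A tibble: 1 × 10
#>   start length_aa length_nt traversals stop_codon ires_proximal ...
#> 1   380       603      1812          1 UAA        TRUE
```

The coding span (1812 nt including the stop) exceeds the 1733-nt circle, so
the ribosome crosses the back-splice junction and terminates on its second
lap — a rolling-circle ORF.

Each result type has `autoplot()`/`plot_*()` methods (volcano,
soft-threshold scan, KM curves, splicing categories, module–trait strip) and
broom-style `tidy()`/`glance()` methods.

## Acceptance script

`scripts/acceptance.R` rebuilds the packaged circHNRNPU fixture circle with
the seeded generator, runs the circular ORF finder at its defaults, and
reports the primary junction-spanning product length:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/circflow-methods.Rmd`) documents the
models, the synthetic-data design and its limitations, and all numerical
choices.
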