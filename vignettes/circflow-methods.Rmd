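---
title: "Methods: models, synthetic data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circflow)
```

`circflow` implements a circRNA biomarker-discovery pipeline: differential
screening of a probe-by-sample cohort, weighted co-expression module
detection, relief-based hub-probe selection, circular ORF prediction across
the back-splice junction, alternative-splicing quantification, and survival
stratification. This vignette is the package's own account of the models it
implements, the synthetic world its generators state, and the numerical
decisions taken where the design was genuinely open. Nothing here reports an
empirical number that the test suite or the acceptance script does not
itself compute.

## The analysis models

### Differential screening

Probes are kept when their linear (FPKM-like) expression exceeds 1 in at
least three samples. Two-group testing uses the Welch (unequal-variance)
t-statistic on `log2(value + 1)` with Satterthwaite degrees of freedom —
chosen over the pooled-variance form because group sizes of 3–5 make the
equal-variance assumption both uncheckable and consequential. The pseudocount
avoids `log(0)` on linear-scale data; it is a parameter
(`pseudocount = 1`) so exact analytic cases can set it to 0. The up/down
call uses the raw p-value (`p < 0.05`) together with the linear-mean fold
change (`> 2` or `< 1/2`): the discovery convention this mirrors states its
cutoff on raw p, so the BH q-value is reported alongside rather than used
for the call. Whether the fold-change gate is on linear or log-scale means
is genuinely ambiguous in the field; the linear-mean convention is used and
the log2 difference of means is also reported. A probe with zero variance
and zero mean difference in both groups is reported with `p = 1` by
convention (no evidence against the null, rather than an undefined
statistic).

### Co-expression network

The network core is written from scratch (it is the analytical substance of
the module stage, not a commodity step). The network is unsigned,
`a_ij = |cor|^β` on Pearson correlations of `log2(value + 1)` — unsigned
being the historical default where the upstream study names only the method
family. The soft-threshold scan fits `log10 p(k) ~ log10 k` over ten
equal-width connectivity bins and picks the smallest power reaching
R² ≥ 0.85, falling back to the argmax. Two practical guards matter on
moderate-size simulated data:

* High powers collapse connectivity toward zero, and the degenerate
  distribution looks scale-free (R² keeps rising as the network fragments).
  The pipeline therefore only trusts powers whose mean connectivity is at
  least 1, and otherwise uses the canonical unsigned default β = 6 — the
  standard fallback recommendation when a scan is inconclusive.
* Topological overlap follows the standard form
  `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with unit
  diagonal, and is property-tested against a triple-loop oracle.

Modules come from average-linkage clustering on `1 − TOM` with a **static
cut at dissimilarity 0.98**. The rationale: pairs with near-zero topological
overlap sit on a plateau immediately below `1 − TOM = 1`, while even weakly
cohesive modules merge well below it, so a fixed cut just under the plateau
separates structure from background without the instability of adaptive
rules. A quantile-based cut was considered and rejected: most merges in a
structured matrix are within-module, so any fixed quantile of merge heights
lands inside modules and splits them. A largest-gap rule
(`cut_height = "gap"`) is retained as an option; it is clean when module
strengths are homogeneous but brittle when they are not. Clusters smaller
than `min_module_size = 10` go to grey; surviving modules are named by
decreasing size with the conventional colour order (turquoise, blue, brown,
yellow, green, ...), ties broken by the lexicographically smallest member
probe id so detection is invariant to input order. Dynamic tree cutting and
eigengene-based module merging are deliberately out of scope.

Module eigengenes are the first principal component of the per-probe
z-scored module submatrix, unit-variance, sign-oriented so the mean member
correlation is positive. Module–trait association is the Pearson correlation
of each eigengene with a binary trait, with the two-sided p from the
t-transform on `n − 2` degrees of freedom; a module is flagged "trait-up"
when the correlation is positive and `p < 0.05`. At that alpha, null
modules false-flag at about 2.5% each — the tests treat an occasional extra
flag as the expected behaviour of the stated rule, not a defect.

### Hub screening

ReliefF in Kononenko's multi-class form: features min-max scaled to [0, 1],
Euclidean distances, `k = 5` nearest hits and per-class misses (k shrinks to
`min(class size) − 1` for the 3-sample NPC group), miss contributions
weighted by `P(c) / (1 − P(class_i))`, averaged over **all** instances — no
subsampling, so the ranking is a deterministic function of the data and
labels. Ties in the final ranking break lexicographically by probe id. The
top 25 probes form the hub panel; the samples are then clustered by
average linkage on `1 − cor` between samples (computed on per-probe z-scored
values, the heatmap convention) and the tree is cut to the number of true
groups, scored by the adjusted Rand index.

### Circular ORFs

Coordinates are 1-based circular with position 1 the first nucleotide
downstream of the back-splice junction (so "+201" style IRES coordinates
read directly). Every AUG is a candidate start (near-cognate starts
excluded); codons are read on the conceptually repeated sequence until the
first in-frame stop or until `max_traversals = 4` junction crossings, after
which the call is flagged unterminated (`stop_codon = "none"`) rather than
dropped — on circles whose length is divisible by 3, an ORF surviving one
full lap can never terminate. The `traversals` field counts junction
crossings before the stop completes:
`floor((start − 1 + length_nt − 1) / L)`. The primary ORF is the first
junction-spanning call after sorting by product length (descending) and
start (ascending). Nested in-frame starts are reported as separate calls;
suppression is a downstream choice, not the finder's. The finder is
property-tested against a naive scan of concatenated copies for all circle
lengths 9–60.

The packaged circHNRNPU-like fixture is a 1733-nt circle, IRES 201–374,
with the planted start at 380 — just downstream of the IRES (the exact
endogenous start coordinate is not public; IRES-proximal placement is the
documented assumption, and `annotate_ires()` marks starts within 60 nt
downstream of the IRES as proximal, boundaries inclusive). The planted
product is 603 aa, so the coding span (1812 nt with the stop) exceeds the
circle and the reading terminates on its second lap — one junction crossing
by the counting rule above.

Junction-unique peptides use a trypsin digest (cleave after K/R except
before P, optional missed cleavages) and subtract the linear isoform's
peptides; peptides shorter than 6 residues are dropped, the usual
MS-detectability floor.

### Alternative splicing

Isoform pairs are typed by exon-chain comparison: skipped exon (SE),
alternative donor/acceptor (A5SS/A3SS, strand-aware: the donor is the exon
end on `+` and the exon start on `−`), retained intron (RI), mutually
exclusive exons (MXE); identical chains are `none` and anything else is
reported `complex` rather than force-fitted. PSI uses effective-length
normalization with defaults (2, 1) — two inclusion junctions versus one
skipping junction for an SE event. Differential testing pools counts within
condition and applies the two-sided Fisher exact test per event with BH
correction; at 2–3 replicates a pooled exact test is more robust than a
replicate-level t-test on PSI, and per-replicate PSI values are still
reported. The RIP intersection keeps significant events whose transcript is
in the bound set, ranked by `|ΔPSI|`.

### Survival and enrichment

Expression dichotomization defaults to a median split (the median itself
low), with a tertile-extremes alternative; the original cohort splitting
rules are not described, so the default is the most common convention.
Kaplan–Meier estimation and the two-group log-rank test are computed via the
`survival` package behind the package's own interface, with hand-worked
small examples as test oracles; ties follow the standard `d_i/n_i`
convention and the log-rank p comes from the 1-df chi-square approximation,
adequate at the simulated cohort sizes. Over-representation analysis is the
upper-tail hypergeometric p per gene set with BH correction.

## The synthetic world

The generators state one fixed world; none of their defaults is tuned to
any test outcome, and all of the following was fixed before the tests were
written.

**Expression cohorts** (`sim_expression()`): the default cohort is 3 NPC /
5 IgD / 5 IgG samples with 2000 probes; seven planted modules of sizes 60,
50, 45, 40, 35, 30, 25; within-module correlation 0.7 via one Gaussian
latent factor per module with loading `sqrt(0.7)`; technical noise sd 0.25
on the log2 scale; baseline `N(3, 1)` so linear values are FPKM-like
(`2^gaussian`, median ≈ 8). Two modules (size ranks 1 and 5, so they surface
as turquoise and green) are IgD-upregulated with factor group means
(NPC, IgG, IgD) = (−2, 0, +2) and (+1, −2, +2), scaled so the group means
carry 75% of the factor's unit variance. The second pattern is deliberately
not the mirror of the first: both are clearly IgD-high, but their weighted
pattern correlation is modest (~0.36), and each disease factor's residual is
orthogonalized against the other's realized factor so sampling noise cannot
fuse the two modules in the network stage. Disease-module members mix
regulation direction (30% load negatively — unsigned modules in real data
contain anti-correlated members) and carry probe-specific group offsets
(sd 0.4): both properties are what allow a correlation-distance sample
clustering on an IgD-up panel to separate three groups at all, since a
uniformly up-regulated panel's group signal sits entirely in the per-sample
profile mean, which Pearson correlation removes. Default fold-change spikes
plant 100 probes at log2FC +2 and 100 at −2 in IgD among background probes
(the volcano's two arms); the co-expression preset
(`coexpression_preset()`: 12/20/20 samples, 600 probes) omits them so the
module structure is exactly the stated seven modules — co-regulated DE
blocks would otherwise be real extra modules.

**Circles** (`sim_circle()`): the builder writes the start codon, keeps body
codons stop-free, writes the stop, and removes upstream in-frame AUGs, using
a constraint-repair loop because rolling-circle traversals revisit the same
positions in shifted frames; the result is verified by re-running the ORF
finder and regenerating on failure. Specs whose coding span exceeds a
length-divisible-by-3 circle are rejected as infeasible (the stop would
collide with an earlier body codon in the same frame).

**Splicing counts** (`sim_as_counts()`): event types from a stated mix
dominated by exon skipping (SE 0.60, A3SS 0.12, A5SS 0.10, RI 0.10,
MXE 0.08, near the reported SE share of such screens); baseline PSI uniform
on (0.05, 0.95); 15% of events shifted by ±0.3 PSI in condition 2; total
junction reads Poisson with mean depth 50 per event and replicate, 3
replicates per condition; the inclusion-read probability is
effective-length-weighted so the PSI estimator is consistent.

**Survival** (`sim_survival()`): log-normal expression
(`meanlog = log(5)`, `sdlog = 0.8`); exponential event times with the hazard
multiplied by the hazard ratio (default 2) above the median expression;
baseline mean survival 60 months; independent uniform censoring with the
upper bound solved numerically to hit the requested censored fraction
(default 20%) in expectation.

**Gene sets** (`sim_genesets()`): random sets over a 2000-identifier
universe plus one planted set holding 80% of a 100-gene hit list.

What a green test does and does not establish: the generators emulate the
*statistical structure* of the original inputs — group design, module count,
disease-module orientation, junction-count noise, expression-linked
hazard — not their biology. Passing tests demonstrate that the
implementation recovers planted truth under the stated model (correct
formulas, calibrated nulls, recoverable structure at realistic
signal-to-noise); they cannot certify performance on real microarray or
RIP-seq data, where normalization artifacts, batch effects, correlated
noise and annotation error exist and are out of scope here (raw-array
normalization and read alignment are explicitly not implemented).

## Numerical choices and degenerate inputs

* Seeding: every generator restores the caller's RNG state; the pipeline
  fans one seed out per stage by a fixed integer derivation kept below
  2^31, so stages are independently reproducible.
* Zero-variance probes are dropped (with a warning) before correlation
  networks; constant features receive exactly zero ReliefF weight; a
  constant trait or all-identical expression is an error, not a silent 0.
* `compute_psi` is undefined (NA) when both counts are zero; zero-count
  events are excluded from differential splicing with a warning.
* Tie-breaking is lexicographic on identifiers everywhere a ranking can
  tie (hub selection, RIP ranking, module naming), making outputs stable
  under input permutation.
* The tests scale simulation sizes to run on one CPU in a few minutes
  (e.g. 300-seed log-rank null, 25-seed DE null, 5x1000-event splicing
  null); the statistical assertions use tolerances appropriate to those
  sizes, stated in each test.

## Known limitations

* The static 0.98 TOM cut assumes the unstructured plateau sits above it;
  extremely weak modules (realized member correlation well below ~0.5 at
  power 6) would be sent to grey.
* The network stage implements a single-matrix network; joint circRNA+mRNA
  "combined" networks, dynamic tree cutting, eigengene merging and
  blockwise decomposition for very large matrices are non-goals.
* ReliefF is deterministic by using all instances; for cohorts far larger
  than the simulated ones a subsampled variant would be preferable.
* The Fisher-based differential-splicing test treats reads as independent;
  overdispersion across replicates is not modelled (pooled counts, as
  stated), which is anticonservative on strongly overdispersed data.
* IRES intervals are annotations, not predictions; no de novo IRES or
  m6A-mediated translation modelling is attempted.
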