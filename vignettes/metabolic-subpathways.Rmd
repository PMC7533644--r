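---
title: "Mining and scoring metabolic subpathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and scoring metabolic subpathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In disease, genes rarely go wrong one whole pathway at a time: dysfunction
concentrates in local subregions of canonical pathways. Testing whole KEGG
metabolic pathways (tens to hundreds of genes) dilutes such localized
signal, while single-gene tests ignore the topology that makes neighboring
enzymes functionally coupled. `metaspw` works at the intermediate scale: it
extracts *metabolic subpathways* — compact gene neighborhoods of a
pathway's enzyme network — scores their activity in every sample of an
expression study, and asks which subpathways separate two phenotype groups
consistently across independent cohorts.

```{r, eval = FALSE}
library(metaspw)
```

## From KGML to an enzyme graph

Each KGML pathway file is reduced to an undirected graph on genes
(enzymes). Two genes are joined when some reaction catalyzed by one and
some reaction catalyzed by the other involve at least one common compound;
substrates and products both count and reaction direction is ignored,
because functional adjacency in a metabolic map — one enzyme's product
feeding another's reaction — does not depend on the arbitrary orientation
a reversible reaction was written in. Genes co-catalyzing a single
reaction are joined through that reaction's own compounds. A KGML entry
listing several gene identifiers is expanded so every gene becomes its own
node, inheriting the entry's reactions: subpathway membership is defined
at the gene level, and expression data is gene-level too.

Two deliberate defaults:

* **No currency-compound filter.** Ubiquitous metabolites (ATP, H2O, ...)
  can create dense hub connectivity, but filtering them changes the graph
  in ways that are hard to standardize; the constructor applies no filter
  unless the user passes `exclude_compounds`, so the default matches the
  plain shared-compound rule.
* **Verbatim identifiers.** KGML gene ids (e.g. `hsa:4047`) pass through
  untouched; `map_gene_ids()` applies a user-supplied two-column table when
  expression matrices live in another namespace (symbols). Mapping is
  data, not code.

Signaling-style `relation` elements are ignored: only reaction/compound
mediated edges are built, which is what "metabolic" means here.

## k-clique subpathways

A subpathway is a maximal set of genes whose pairwise shortest-path
distance in the enzyme graph is at most `k` — the *k-clique* of social
network analysis (not the clique-percolation notion of the same name).
The default `k = 4` extracts stable neighborhoods whose members still
share function; smaller `k` gives tighter, more fragmented sets, and the
parameter is exposed for users who want either extreme.

The implementation reduces the definition to a standard primitive: build
the *distance closure* (join every pair at distance `<= k`; pairs in
different components stay unjoined), then enumerate maximal cliques of the
closure with Bron–Kerbosch pivoting (via `igraph`). Sets smaller than
`min_size = 3` are discarded after maximality — singleton and pair
"subpathways" carry almost no enrichment information — and `min_size = 1`
restores the unfiltered definition.

Determinism is part of the contract: cliques are ordered by decreasing
size, ties broken by the lexicographic gene list, and labelled
`<pathway>_<index>` with 1-based indices. Published labels from other
tools depend on their KEGG snapshot and internal ordering, so label
equality across tools is not a goal; label stability across runs is.
Overlapping subpathways are kept as-is (maximal cliques overlap by
nature); no merging step is applied.

## Activity scores

Scoring follows the unsupervised single-sample enrichment construction of
GSVA. For gene $i$ with values $x_{i1},\dots,x_{in}$:

1. **Kernel CDF.** Continuous data (microarray intensity, log-FPKM) uses a
   Gaussian kernel,
   $z_{ij} = \frac1n \sum_m \Phi\!\big(\frac{x_{ij}-x_{im}}{h_i}\big)$,
   with bandwidth $h_i = s_i/4$ ($s_i$ the sample SD with $n-1$
   denominator). Integer counts (RNA-seq) use a Poisson kernel,
   $z_{ij} = \frac1n \sum_m F_{\text{Pois}}(x_{ij};\, x_{im} + 0.5)$,
   the 0.5 offset keeping the rate positive at zero counts. `kcdf = "auto"`
   picks the Poisson kernel exactly when every value is a non-negative
   integer. Both kernels place every gene on a common (0, 1) scale, which
   is what lets cohorts from different platforms be analyzed with the same
   machinery. Constant genes have no bandwidth and are removed with a
   warning rather than scored.
2. **Symmetric ranks.** Per sample, genes are ranked by decreasing
   $z$ (largest $z$ gets rank $p$; ties keep input order, so runs are
   reproducible), and the statistic $r_{ij} = |p/2 - \text{rank}_{ij}|$
   up-weights both extremes of the ranking. The exponent $\tau$ (default
   1) tunes that weighting.
3. **KS-like walk.** Walking genes in decreasing-$z$ order, the deviation
   after $\ell$ steps is the weighted fraction of the gene set seen so far
   minus the fraction of non-members seen so far. The activity score is
   the maximum positive deviation plus the minimum negative deviation
   (equivalently the difference between the maximum and minimum
   enrichment deviations), giving a score in $[-1, 1]$ whose sign says
   whether the set concentrates at the top or bottom of the sample's
   ranking. The walk always returns to 0 at $\ell = p$.

Under the null of no coordinated change, the score is expected to be
centered and symmetric; the test suite checks exactly that (mean and
skewness of scores for random gene sets on i.i.d. normal data, 1000 genes
by 30 samples, 50 sets of size 10) rather than asserting full normality
or unit variance, which finite samples cannot pin down.

Gene sets are intersected with the matrix before scoring (absent members
dropped with a logged count, sets falling below `min_set = 2` dropped
with a warning); an $n = 1$ matrix is rejected because a one-sample
kernel CDF estimate is meaningless.

## Differential activity and cross-cohort intersection

Per cohort, each subpathway's activity is compared between two groups with
a moderated t-statistic: the pooled two-sample variance $s_g^2$ (on
$d_g = n_1+n_2-2$ df) is shrunk toward a prior $s_0^2$,
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
$\tilde t_g = \Delta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ is referred to
$t_{d_0+d_g}$. The prior is fitted by the method of moments for a scaled-F
model of the observed variances: $d_0$ solves
$\psi_1(d_0/2) = \mathrm{var}(\log s_g^2) - \psi_1(d_g/2)$ by monotone
Newton root-finding on the trigamma inverse, and $\log s_0^2$ comes from
the mean of $\log s_g^2$ with the matching digamma correction. When the
observed spread of variances is no larger than sampling noise predicts,
$d_0 = \infty$ is represented explicitly: every row gets the common
variance and p-values become normal. `prior_df = 0` recovers the
classical pooled t exactly, which the tests verify against `t.test()`,
and the full fit is cross-checked against an independent implementation
of the same empirical-Bayes construction.

Multiple testing uses Benjamini–Hochberg by default (Bonferroni
available), significance is strict (`adj_p < alpha`, default 0.05), and
with several cohorts only subpathways significant in *every* cohort are
reported. Direction consistency (up in all cohorts or down in all) is on
by default — a subpathway flipping sign across cohorts is more plausibly
artifact than biology — and can be disabled for a literal id
intersection.

## What the synthetic generator emulates — and what it does not

`simulation_spec()` + `generate_pathways()` + `simulate_expression()`
produce the one statistical structure the method is built to detect: a
coordinated mean shift of one subpathway's genes in one group, against
i.i.d. background. Defaults describe a 20 vs 20 two-group study, ten
10-gene pathways, standard-normal noise, and one implanted subpathway
shifted by 1 SD — a realistic effect size for a strongly dysregulated
metabolic module in tissue data. The default `hub` topology makes every
pathway mine to exactly one subpathway, so the ground truth of a recovery
experiment is unambiguous; `chain` and `random` topologies exercise the
mining distance bound instead. 100 unannotated background genes are
appended so per-sample rankings are not dominated by pathway genes;
count-mode noise is negative binomial (dispersion 0.1) rather than pure
Poisson so overdispersion stresses the Poisson kernel the way real
RNA-seq would.

Deliberately *not* emulated: gene–gene correlation within the background,
probe/platform effects, library-size variation, real cohort sizes, or any
GBM biology. Passing recovery tests therefore demonstrates the machinery
— mining, scoring, testing, intersecting — not performance on real
tissue cohorts.

Generated KGML files encode each designed edge as a unique compound shared
by exactly the two endpoint reactions, so parsing and graph construction
reproduce the designed topology node-for-node; this round-trip is asserted
in tests. All generation is seeded and byte-reproducible; `seed` is
mandatory.

## Numerical choices and degenerate inputs

* SDs use the $n-1$ denominator; bandwidth $h_i = s_i/4$; Poisson offset
  0.5; $\tau = 1$ — all exposed as arguments, none silently changed.
* Rank ties break by input gene order (stable), making scores identical
  across platforms and runs.
* Zero-variance activity rows under `prior_df = 0` have no defined
  statistic; they propagate `NaN` with a warning instead of a fabricated
  p-value.
* Probe collapsing removes probes containing any zero before averaging
  probes of a gene — appropriate for array intensities where zeros mean
  detection failure; for counts the filter must be disabled
  (`drop_zero_probes = FALSE`) and the error message says so.
* Empty graphs mine to empty collections; reactions that reference no
  known gene entry are skipped with a warning; malformed XML fails loudly
  with the file name.

The validation suite runs at deliberately small scale — random graphs up
to 30 nodes (100 of them) for the distance-bound check, up to 12 nodes
against a brute-force subset-enumeration oracle, 200 random walk
instances at $p \le 20$, a 1000 × 30 null matrix, and 50 simulation seeds
for end-to-end recovery — sizes chosen so the whole suite re-derives
every expected value from scratch in minutes while still exercising every
code path at realistic shapes.

## Known limitations

* **Compositional coupling of scores.** Rank-based single-sample scores
  are relative within a sample: genuinely up-shifting one gene set pushes
  every other set's members down the ranking, so strong signal in one
  subpathway induces small opposite-direction shifts in others. In
  simulations this shows up as occasional spurious "down" calls alongside
  a strong implanted "up" signal. Cross-cohort intersection damps but
  does not eliminate this; users should read weak calls that mirror a
  strong opposite signal with care.
* **Snapshot dependence.** Mined subpathways (and their `_index` labels)
  depend on the KGML files provided; different KEGG releases give
  different collections by design.
* **Overlap.** Maximal cliques overlap; downstream tests on overlapping
  subpathways are correlated, and no overlap correction is applied.
* Only reaction/compound edges are modeled; signaling relations, enzyme
  complexes, and stoichiometry are out of scope, as are survival analysis
  and clustering of the activity matrix.
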