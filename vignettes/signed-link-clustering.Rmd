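---
title: "Signed link clustering: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed link clustering: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siglinc)
```

## The model

A signed undirected network carries one sign per unordered node pair:
+1 (coexpression, alleviating genetic interaction) or −1
(anti-coexpression, synthetic lethality). Positive and negative links play
asymmetric structural roles — positive links aggregate into dense clusters,
negative links tend to bridge between them — and the package's statistics
are built to expose that asymmetry at the level of individual edges.

### Link-clustering coefficients

For an edge e = (i, j) let n(i) and n(j) be the *excess* neighbor counts
(the partner node excluded), and classify every common excess neighbor k by
the sign pair of the two links (i, k) and (j, k): both positive (count
c_pp), both negative (c_nn), or mixed (c_hy). With d = min(n(i), n(j)):

* LC  = (c_pp + c_nn + c_hy) / d — sign-blind shared-neighbor proportion;
* SLC = (c_pp + c_nn) / d — same-sign part; HLC = c_hy / d — hybrid part;
* PLC = c_pp / d and NLC = c_nn / d — the positive and negative subtypes of
  SLC.

**Denominator convention.** A proportion of shared neighbors needs a
normalisation, and two defensible choices exist once signs enter. The
default, `min_total`, uses the single denominator d = min(n(i), n(j)) for
all five coefficients. This is the convention under which the decomposition
identities LC = SLC + HLC and SLC = PLC + NLC hold exactly edge by edge
(the package constructs LC and SLC from the subtypes so the identities are
exact in floating point too, and the test suite asserts them as
identities). The alternative, `min_signed`, normalises each subtype by the
matching sign-specific excess counts — PLC by min(n⁺(i), n⁺(j)), NLC by
min(n⁻(i), n⁻(j)), HLC by min(n⁺(i), n⁻(j)) + min(n⁻(i), n⁺(j)) — which
asks "how many such neighbors *could* there have been of that sign" rather
than "of any sign". Each subtype count is bounded by its signed denominator,
so `min_signed` coefficients also stay in [0, 1], but the decomposition
identities need not hold. `min_signed` exists for sensitivity analysis; all
downstream machinery uses `min_total` unless told otherwise.

**Degenerate edges.** A pendant edge has d = 0; 0/0 is defined as 0 rather
than smoothed away with a +1 in the numerator, because exact zeros are
informative here (a pendant edge genuinely shares nothing). Medians use the
usual midpoint convention for even counts.

### Structural balance and what is actually forced

A network is (strictly) balanced when its nodes split into **two** groups
with all-positive links inside and all-negative links between. In that case
three zero-invariants are structural theorems, not tendencies: every
negative edge has SLC = 0, every positive edge has HLC = 0, and the triad
census contains no ++− (T3) or −−− (T4) triangles. With three or more
groups (weak balance) the picture changes: a negative edge between groups A
and B can reach a common neighbor in group C through two negative links, so
SLC(−) > 0 and −−− triangles occur; only HLC(+) = 0 and the absence of T3
remain forced. The test suite asserts the strict claims on two-block
constructions and the weaker ones on multi-block constructions — a
distinction worth keeping in mind when interpreting real networks, which
are at best approximately balanced.

### Triad census and the sign-shuffle null

Triangles are classified by their sign multiset (T1 = +++, T2 = +−−,
T3 = ++−, T4 = −−−). The null model permutes the multiset of signs over the
fixed topology, preserving the positive/negative counts and every
topological quantity including the total triangle count. Under this null
the expected count of a type is the total triangle count times a
multivariate hypergeometric probability — drawing 3 signs without
replacement from (M⁺, M⁻) — which `expected_triad_counts()` evaluates in
closed form and the simulation is tested against (within 3 standard errors
at 10,000 shuffles). Defaults: 1,000 shuffles; empirical p-values use the
add-one convention p = (1 + #{null ≥ observed}) / (B + 1), so p is never
exactly zero; both tails are reported. Each shuffle draws from a seed
derived as `seed + shuffle index`, making per-shuffle results independent
of evaluation order.

### Common-neighbor profiles

For each negative edge, every hybrid common neighbor defines a link pair
with one positive and one negative member. The per-edge medians of the
positive members' PLC and the negative members' HLC, correlated against the
edge's own HLC across all negative edges, quantify whether strongly
hybrid-clustered negative links bridge denser positive clusters.
Correlations are reported as undefined (NA) when fewer than three profile
rows exist or a variable is constant — which happens by construction on the
complete two-block network, where every negative member's HLC is exactly 1
and every positive member's PLC is exactly 1/4 (one same-block and three
cross-block common neighbors over d = 4).

### Link communities and partition density

Positive links are clustered by the score S_e = PLC_e + NLC_e (equal to
SLC_e under the default convention): ranking links by score in descending
order and cutting at score s retains links with S_e ≥ s and merges retained
links that share a node (single linkage on the line graph). The cutoff is
chosen to maximise Ahn et al.'s partition density

D = (2/M) Σ_c m_c (m_c − (n_c − 1)) / ((n_c − 2)(n_c − 1)),

a link-count-weighted mean of per-community densities normalised so trees
score 0 and cliques 1; communities of two nodes contribute 0. During the
sweep, M is the number of links retained at the cutoff, so a partition of
the retained links into cliques scores exactly 1 and links excluded by the
cutoff neither help nor dilute. The threshold sweep is an interpretation of
"single-linkage clustering of ranked links": it reproduces the
dendrogram-cut semantics without defining a pairwise link–link similarity;
the pairwise-Jaccard dendrogram of Ahn et al. is a known alternative that
this package deliberately does not implement. Ties at the maximal D go to
the largest (most stringent) cutoff by default, so reported modules are
minimal; `tie_rule = "inclusive"` flips that. Modules are link communities
whose gene set (union of endpoints) has at least `min_genes = 3` genes.
Link communities are edge-disjoint but may share genes; the module map
counts a link as inter-module only when it is internal to neither module,
and densities use each module's own gene count.

## Network builders

**Coexpression.** Pairwise Pearson correlations use pairwise-complete
observations with a minimum of 10 complete pairs (expression matrices in
public repositories contain missing values; pairs below the minimum or with
zero variance are excluded as undefined, not set to 0). Thresholding at
PCC ≥ 0.9 / ≤ −0.9 keeps ties at the threshold, and genes with no retained
link are dropped from the node set. The computation is blockwise over gene
chunks to bound memory, with results identical to the naive all-pairs
computation (asserted in the tests). No normalisation, log transform, or
probe collapsing is applied — the input is taken as the analysis-ready
matrix, and results on public expression series will depend on those
upstream choices.

**Genetic interactions.** BioGRID-style tab files are parsed with
configurable 1-based column indices (defaults: systematic names in columns
6/7, experimental system in column 12, organism in 16/17). The default sign
map sends "synthetic rescue" and "positive genetic" to +1, "synthetic
lethality" and "negative genetic" to −1, case-insensitively; unmapped
labels are ignored. Pairs supported by both signs are *ambiguous* and
removed entirely — the standard curation step for genetic-interaction
data — with counts reported. Identifiers are opaque case-sensitive strings;
no symbol normalisation or organism defaulting is attempted, and both the
identifier columns and the taxon filter are exposed as options because
releases differ.

## The synthetic generators

The generators provide ground truth the analyses can be scored against.

* `balanced_block_network(sizes, p_in, p_out, epsilon, seed)` plants the
  canonical balanced construction and then flips each sign with probability
  ε. The module-recovery conditions used throughout (four blocks of 20
  genes, p_in = 0.8, p_out = 0.3, ε = 0.05) emulate a dense
  genetic-interaction neighborhood with a realistic minority of
  sign-discordant measurements; recovery is scored as the per-block best
  Jaccard against the discovered modules (median ≥ 0.9 over 20 seeds is the
  tested bar, and in practice recovery is exact on most seeds).
* `random_signed_network(n, p, positive_fraction, seed)` gives signs
  independent of topology, so every triad fold is 1 up to sampling noise —
  a self-consistency check for the null.
* `planted_module_expression()` builds modules in anti-phase pairs from
  latent sample profiles z_q = (d_q + w_q)/√2, where d_q is a two-level
  condition contrast (alternating orientation between pairs) and w_q is
  white noise; genes add independent N(0, τ²) noise. τ is derived from the
  target within-module correlation (τ = √(var(z)(1/r − 1)), using the
  realized latent variance so the expected sample correlation hits the
  target), and the anti-phase partner is attenuated by
  γ = |between_r|/within_r. Defaults within_r = 0.95, between_r = −0.95
  give γ = 1, so the noise-free limit produces exactly +1 within modules
  and −1 across anti-phase pairs, and thresholding at |PCC| ≥ 0.9 recovers
  the planted edge set exactly. Targets with |between_r| > within_r or
  between_r > 0 are infeasible under this construction and error.

What the generators do *not* emulate: scale-free degree structure, the
heavy overlap of real functional modules, correlated measurement error
across samples, or any realistic number of probes and conditions. Passing
tests on these constructions shows the algorithms are correct on networks
with known structure, not that any particular biological dataset will
yield clean modules.

One empirical nuance found while validating: the coupling between an
edge's SLC and its underlying PCC in a planted coexpression network is a
reliable positive correlation, but the *bin-median* curve is not strictly
monotone at fine granularity — the min-degree denominator saturates SLC for
barely-connected genes, contaminating the top bin. The property tests
therefore assert the half-split median ordering and the positive
correlation per seed rather than fine-binned monotonicity.

## Numerical and design choices

* Canonical edge keys are lexicographically sorted node pairs; all tables
  iterate in that order, making outputs deterministic byte for byte.
* Tie-breaking when ranking edges by coefficient (context curves, Fisher
  enrichment) is stable by canonical edge key.
* The Fisher enrichment odds ratio is the sample odds ratio with the
  Haldane half-count correction when a cell is zero; degenerate tables
  (all or no edges annotated) are flagged with p = 1 rather than tested.
  The calibration simulation uses 10,000 edges per replicate so the
  discrete conditional null is near-continuous and the attained one-sided
  size sits just below the nominal 0.05.
* Simulation sizes in the tests (graphs of up to ~30 nodes for
  oracle-equivalence, 10,000 shuffles for the null closed-form check,
  20 seeds for module recovery, 10,000 replicates for Fisher calibration)
  were chosen to make the statistical assertions sharp at desk scale.
* All generator and analysis randomness flows through explicit integer
  seeds; generators restore the caller's RNG state.

## Known limitations

* Coefficient computation is O(Σ_e (deg(i) + deg(j))) in pure R; networks
  with hundreds of thousands of edges will be slow. The algorithms are
  simple enough to port to C++ if that becomes limiting.
* The sweep recomputes connected components per distinct score level
  rather than maintaining an incremental union-find; with many distinct
  score values on large networks this is the dominant cost.
* Only per-link score thresholding is implemented for link clustering (see
  above); results can differ from a pairwise link-similarity dendrogram.
* The printed equations of the coefficient denominators admit the two
  conventions discussed; `min_total` is the package's documented default,
  chosen for its exact decomposition identities, not asserted as the only
  possible reading.
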