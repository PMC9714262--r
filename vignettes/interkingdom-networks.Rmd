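---
title: "Methods: interkingdom co-abundance networks for paired microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interkingdom co-abundance networks for paired microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadnet)
```

This vignette is the package's own account of its statistics: the models and
procedures, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. Data model

A cohort consists of two `taxa_table`s — taxa × samples counts for bacteria
(genus-level labels, the resolution 16S amplicons support) and fungi
(species-level, per ITS2) — plus per-sample metadata carrying the dyad
structure: each mother–infant pair contributes a milk sample (the mother's)
and fecal samples at 1 and 6 months (the infant's), with birth mode and four
antibiotic-exposure flags (prenatal, perinatal, maternal postpartum, infant
postnatal). Analyses that correlate kingdoms require sample-aligned tables;
`align_paired()` intersects rosters and reports what was dropped and why.
Zero-count samples are dropped at load with a warning rather than imputed.

## 2. Compositional diversity

Counts are compositions: only relative information is meaningful. The
centered log-ratio transform maps each sample to
$x_{ij} = \ln(c_{ij} + \epsilon) - \tfrac{1}{T}\sum_i \ln(c_{ij} + \epsilon)$,
and **Aitchison distance** is the Euclidean distance between CLR columns.

* **Pseudocount** $\epsilon$ (default 1, added to every count): required for
  zeros; the source methodology is silent, and 1 is the dominant convention.
  It is a config knob recorded in output provenance. CLR columns sum to zero
  by construction (tested to 1e-9).
* **Alpha diversity**: Shannon entropy $-\sum p_i \ln p_i$ (natural log) and
  Simpson in the complement form $1 - \sum p_i^2$. "Simpson" is ambiguous
  across software; the complement form is stated prominently wherever it is
  reported.
* **Bray–Curtis** on proportions and **unweighted UniFrac** (unshared branch
  length over the union's branch length, presence = count ≥ 1, rooted tree
  with branch lengths required) are provided because ordination pairs in this
  analysis family are built on any of the three metrics. No rarefaction
  anywhere: diversity is computed on full counts/proportions.
* **PCoA** is classical metric scaling: eigendecomposition of the
  double-centered $-D^2/2$. Axes with negative eigenvalues (possible for
  Bray–Curtis and UniFrac, impossible for Aitchison) are discarded and their
  total magnitude kept in the result, so distortion is explicit rather than
  corrected (no Cailliez adjustment).

## 3. PERMANOVA

`permanova()` Gower-centers $G = -\tfrac12 J D^2 J$ and partitions
$\mathrm{tr}(G)$ sequentially (Type-I) over an ordered term list via
cumulative projection hat matrices; pseudo-$F_k$ uses the residual of the
full model. Significance is by free permutation of sample labels with
$p = (\#\{F^\pi \ge F\} + 1)/(n_\pi + 1)$; an `exact = TRUE` mode enumerates
all $n!$ permutations for $n \le 7$ (used by the oracle tests).

Decisions: sequential SS with user-controlled order matches
adjusted-covariate language while keeping the decomposition exact
($\sum SS = SS_{total}$, a tested invariant); free permutation of raw labels
is exact under the global null and the reference method does not specify a
scheme; repeated measures are handled by analyzing sample types separately —
restricted permutation blocks are out of scope and documented as such. Sums
of squares are clamped at zero so degenerate configurations (zero
within-group distances) produce $F = +\infty$ rather than a sign flip from
floating-point noise.

## 4. Dyad similarity

The question "are infants closer to their own mother's milk community than
to other mothers'?" is answered by resampling: the related set holds one
milk→feces distance per dyad; each repetition draws a random **derangement**
(every mother paired with a different dyad's infant, never her own — asserted)
and compares related vs unrelated with a two-sided Wilcoxon rank-sum test
(exact for ≤ 25 tie-free dyads). Defaults: 100 repetitions, summarized by the
median p and the fraction below 0.05, plus a pooled variant (all repetitions'
unrelated distances in one test), each labeled.

**Caveat discovered during calibration and handled explicitly**: the related
set and every unrelated set share the same milk and fecal samples, so the
rank-sum statistic has far less spread than its independence null assumes.
Under a no-dyad-effect generator the per-repetition Wilcoxon p-values pile up
far from the rejection region (the test's measured size is ~0, i.e. it is
strongly conservative — it can only understate dyad similarity, not invent
it). The result therefore also reports `perm_p`, a calibrated derangement
permutation test: the observed mean related distance is ranked among the
per-repetition mean unrelated distances with add-one tail estimates,
two-sided by default. `perm_p` is the recommended significance summary and
is the quantity whose type-I error the acceptance suite verifies.

## 5. Procrustes congruence

Two ordinations over the same samples are compared after centering and
scaling each to unit sum of squares; the optimal rotation (reflections
allowed — the standard choice) comes from the SVD of the cross-covariance,
giving $m^2 = 1 - (\sum_k \sigma_k)^2 \in [0,1]$ and the correlation-style
$t = \sqrt{1 - m^2}$. Significance is Monte-Carlo: rows of one configuration
are randomly permuted and $m^2$ refit; $p = (\#\{m^2_\pi \le m^2\}+1)/(n_\pi+1)$.
The number of axes defaults to all positive-eigenvalue axes available in
both inputs. Which distance metric feeds each kingdom's ordination is run
configuration: the methodology family uses Aitchison throughout in some
reports and unweighted UniFrac (bacteria) with Bray–Curtis (fungi) in others,
so the pairing must be stated per run rather than hard-coded.

## 6. Interkingdom networks — the core

For each analysis subset (sample type, then optionally birth-mode or
antibiotic subgroups, re-filtered *within* the subset):

1. **Prevalence filter**: keep taxa present (count ≥ 1) in at least 30% of
   the subset's samples — boundary inclusive (3 of 10 passes; 2 of 10 does
   not; both are frozen test cases).
2. **Relative abundance**: proportions are computed on the full table before
   filtering (default); renormalizing within the filtered set is available
   (`relative_within = "filtered"`) since the convention is unstated. The
   choice does not move Spearman edges when every sample keeps the same
   denominator, but it does after subgroup re-filtering, hence the switch.
3. **Edges**: Spearman's rho (average-rank, tie-corrected) for every
   bacteria × fungus pair; intra-kingdom pairs are out of scope by design.
   Two-sided p from the t approximation
   $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (exact enumeration for tie-free
   $n \le 7$, which real tables never hit but the oracle tests do);
   $|\rho| = 1 \mapsto p = 0$. An edge is retained iff $p < 0.05$ strictly,
   **uncorrected** — deliberate fidelity to the reference method; a BH mode
   exists (`bh = TRUE`) and is recommended for substantive claims about
   individual edges.
4. **Connectedness** $= |E|/|V|$ exactly, where $|V|$ counts **all**
   prevalence-filtered taxa of both kingdoms, edge-bearing or not
   (`node_mode = "all"`). This is the single most result-sensitive ambiguity
   in the method: counting only connected nodes inflates sparse networks'
   connectedness and makes subgroups incomparable; the all-nodes denominator
   keeps the statistic comparable across subgroups with similar rosters. The
   alternative is available (`node_mode = "connected"`).

**Comparing connectedness between networks.** The reference analyses report
"pairwise t-tests" without a statistical unit. The literal reading — Welch's
t on per-node degree distributions — is provided (`unit = "degree"`) but is
anti-conservative under the null: each edge raises two degrees, so degrees
within a network are positively dependent and the node-level variance
understates the network-level one (measured size ≈ 0.18 at nominal 0.05 in
null simulations). The default (`unit = "edge_rate"`) therefore compares the
per-pair edge rates $|E|/(n_b \times n_f)$ with a conditional binomial mid-p
test — under the null, edge counts are very nearly binomial over pairs
(dependence between pairs sharing a taxon is second-order), and the mid-p
variant holds its nominal size in the same simulations. The chosen unit is
recorded in every result.

Layout uses a plain Fruchterman–Reingold iteration (repulsion $k^2/d$,
attraction $d^2/k$, linear cooling from 0.1 over 100 steps, unit square,
$k = \sqrt{1/n}$), deterministic given its seed. Exports: edge-list TSV and
GraphML with kingdom/sign attributes.

## 7. Differential abundance

Per taxon: two-sided Wilcoxon rank-sum on relative abundances between two
groups, with the Hodges–Lehmann shift estimate (median of pairwise
differences) and its rank-sum-inversion CI. Exact enumeration for combined
$n \le 20$ without ties, tie-corrected normal approximation with continuity
correction otherwise (the crossover matches the oracle-enumerable range; the
continuity correction is a flag since the reference is silent). BH q-values
use the step-up formula $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, one FDR
family per (sample type × contrast) call — never pooled across sample types.
Significance convention: $q < 0.25$.

Compositional differential-abundance methods (ANCOM, ALDEx2) are
deliberately absent: they would change the method under test.

## 8. The synthetic cohort generator

`generate_cohort()` draws, per sample, one multivariate normal over all taxa
of both kingdoms whose correlation matrix encodes the planted
bacteria–fungus edges (a Gaussian copula; positive semi-definiteness is
validated at construction and the offending edge set named otherwise). To
this latent vector it adds per-(taxon, sample-type) baselines, a dyad-shared
shift, and covariate log-fold effects; exponentiation and per-kingdom closure
give a composition; counts are multinomial at a lognormal depth; structural
zeros come from per-taxon Bernoulli thinning. Rationale for the copula:
Spearman's rho is invariant to the monotone exp/closure maps, so a planted
latent correlation is directly interpretable as a target rank correlation,
attenuated only by counting noise and thinning — and the attenuation is
measured by tests, not assumed.

Defaults state the emulated world:

| parameter | default | why |
|---|---|---|
| samples per dyad | milk, feces 1 mo, feces 6 mo | the cohort design |
| depth (lognormal median) | 29,762 / 34,286 bacterial and 7,162 / 6,191 fungal reads (milk / feces) | the per-sample averages typical of such sequencing runs |
| `depth_sdlog` | 0.5 | realistic ~2-fold depth spread |
| `base_logabund_sd` | 1.2 | uneven communities; niches differ in composition |
| `taxon_sigma` | 1.0 | per-sample overdispersion on the log scale |
| `prevalence` | per-taxon U(0.4, 1) | a realistic prevalence gradient around the 30% filter |
| exposure probabilities | cesarean 0.15, prenatal abx 0.22, perinatal 0.25, maternal postpartum 0.20, infant postnatal 0.13 | cohort-realistic frequencies |
| `dyad_effect_sd` | 0 | dyad similarity is an effect to opt into, not a hidden default |

Taxa named in planted edges get prevalence 1: thinning is independent across
kingdoms and would otherwise erode exactly the correlations the cohort is
supposed to carry. For the same reason the "strong planted structure"
scenarios used in congruence power tests set `prevalence = 1` throughout —
structural zeros are, by construction, congruence noise. Covariate effect
sizes are free parameters of the generator, not estimates of any study; the
connectedness-contrast scenario in the acceptance suite plants 8 pairs at
base ρ = 0.45 with a 2× multiplier for exposed dyads (0.9), a
power-calibrated choice mirroring the recovery scenario's "strong" |ρ| = 0.8.

What the generator does **not** emulate: taxonomic identity and phylogeny
(taxa are exchangeable labels; UniFrac tests use separate hand-built trees),
read-level artifacts (chimeras, contamination — a documented exclusion-list
config key stands in for the wet-lab caveat), intra-kingdom correlation
structure, and longitudinal autocorrelation beyond the dyad shift. A green
test therefore establishes that the statistics behave as claimed on sparse
overdispersed compositional counts with planted truth — not that any
biological conclusion transfers.

## 9. Numerical and reproducibility choices

* Every stochastic function takes an explicit seed and restores the caller's
  RNG state; the pipeline expands one top-level seed into per-stage seeds,
  so stages can be rerun in isolation and full reruns are byte-identical
  (tested at the byte level).
* Permutation p-values use the add-one estimator, so $p \ge 1/(n_\pi+1)$ and
  exact zeros are impossible; exact enumeration modes divide by the true
  count instead.
* Ties: average ranks everywhere; tie-corrected Pearson-on-ranks equals the
  standard tie-corrected Spearman.
* Degenerate inputs are errors with names in the message (duplicate ids,
  negative counts with cell coordinates, all-zero samples, constant terms,
  collinear terms, non-PSD edge sets, rosters out of order).

## 10. Known limitations

* Spearman on relative abundances inherits compositional coupling; the
  uncorrected edge rule reproduces the reference method and so also its
  multiplicity behavior (≈ 5% of tested pairs appear as false edges — the
  acceptance suite measures exactly this). Use `bh = TRUE` for claims about
  individual edges.
* The per-repetition Wilcoxon in the dyad test is conservative (Section 4);
  rely on `perm_p`.
* No restricted permutations for repeated measures; analyze sample types
  separately.
* Connectedness comparisons treat the two networks' inputs as independent
  samples; comparing nested subgroups of the same samples is not a valid use
  of either unit.
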