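---
title: "Phylogeny-aware metabologenomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware metabologenomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylolink)
```

## The problem

Paired genomic/metabolomic surveys of natural-product producers yield two
binary incidence matrices over the same strains: which gene cluster
families (GCFs) each genome carries, and which metabolite families (MFs)
each strain produces under the culturing conditions used. Naive
co-occurrence screens (a chi-squared test per GCF x MF pair) link many
pairs spuriously, because closely related strains share both their BGC
complements and their metabolomes for reasons of common descent rather
than function. phylolink implements the phylogeny-aware alternative:
treating each trait as a binary character evolving along the strain
phylogeny and asking whether a GCF and an MF *co-evolve* — whether the
presence of one changes the gain/loss dynamics of the other.

## The correlated-evolution model

A single binary trait follows a two-state continuous-time Markov chain
with gain rate $q_{01}$ and loss rate $q_{10}$ per unit branch length.
For a pair of traits $(A, B)$ we compare two nested models on the joint
state space $\{(0,0), (0,1), (1,0), (1,1)\}$:

* **independent** (4 rates): each trait keeps its own $q_{01}, q_{10}$
  regardless of the partner's state;
* **dependent** (8 rates): each trait's gain and loss rates may differ
  according to the partner's state
  ($\alpha_1, \alpha_2$: gain of $A$ with $B$ absent/present;
  $\beta_1, \beta_2$: gain of $B$; $\gamma_1, \gamma_2$: loss of $A$;
  $\delta_1, \delta_2$: loss of $B$). Simultaneous transitions of both
  traits have rate zero.

Likelihoods are computed by Felsenstein pruning (post-order dynamic
program over partial likelihoods, with per-node rescaling against
underflow), implemented in C++ for the 4-state pair model because the
calibration experiments require thousands of maximum-likelihood fits.
The models are compared by the likelihood ratio statistic
$D = 2(\ln L_{dep} - \ln L_{indep})$ against the chi-squared distribution
with 4 degrees of freedom, at $\alpha = 0.01$.

### Direction: the RQ statistic

A significant LRT only says the traits' dynamics are coupled — it does
not distinguish attraction from repulsion. We operationalize the
direction criterion as **stationary concordance**: with $\pi$ the
stationary distribution of the fitted dependent generator,

$$RQ = \pi_{(0,0)} + \pi_{(1,1)} ,$$

the long-run probability that the two traits agree. Independent
equal-rate dynamics give $RQ = 0.5$; strong positive coupling drives
$RQ \to 1$; anti-association gives $RQ < 0.5$. A pair is called *linked*
iff it is eligible, $p < \alpha$ and $RQ \ge 0.65$. The 0.65 default
keeps only clearly positive associations. This definition is this
package's declared interpretation of the direction filter; alternative
operationalizations (counting rate inequalities) could be wired in
through the same interface, but are not second-guessed here.

### Eligibility

A pair is only testable if both traits carry repeated evolutionary
signal. We require at least `min_changes = 2` state changes per trait,
measured by unit-cost small parsimony (Sankoff) on the rooted tree — an
observable, deterministic stand-in for "at least two gain or loss
events". A trait confined to a single clade (one gain) is ineligible no
matter how well it overlaps a partner: with one event there is no
repeated co-evolution to detect. This mirrors the known failure mode in
which a compound produced by exactly two sister strains cannot be
assigned to its cluster.

### Numerical choices

* **Root prior**: uniform over states (configurable to stationary). With
  sparse traits the stationary prior couples the root strongly to the
  rates and biased rate-ratio recovery upward in our simulations
  (median 0.032 vs a true 0.016); the uniform prior recovered 0.020.
* **Tree scale**: trees are rescaled to unit mean root-to-tip depth
  before fitting; rates are reported per unit depth and rate *ratios*
  are scale-invariant.
* **Optimizer**: L-BFGS-B on log rates, box bounds $[10^{-6}, 10^3]$,
  one fixed start (all rates 0.5) plus log-uniform random restarts
  (default 5 starts), deterministic given a seed. The dependent fit
  additionally starts from the expanded independent optimum, which both
  speeds convergence and guarantees the nesting invariant
  $\ln L_{dep} \ge \ln L_{indep}$ in practice. Ties between restarts are
  broken by highest log-likelihood, then smallest log-rate norm.
* **$D$ is clipped at zero**; degenerate (constant) traits are flagged
  and excluded from rate summaries; likelihood underflow is guarded by a
  $-10^{308}$ sentinel.
* **Multiple testing**: no correction by default, matching the plain
  $\alpha = 0.01$ decision rule of the comparator-versus-phylogeny
  analysis this package reproduces; Benjamini-Hochberg can be applied
  downstream by the user on the reported p-values.

### Small-sample behaviour of the LRT

On trees of a few dozen tips with a handful of events per trait, the
chi-squared(4) reference is **conservative**: in our null calibration
(independent traits, 24-tip trees, eligibility enforced) the observed
rejection rate at $\alpha = 0.01$ was 0-1%, and the null quantiles of
$D$ sat well below their chi-squared counterparts (99th percentile ~7 vs
13.3). The practical consequence is fewer false positives than the
nominal level suggests — the direction that matters for a discovery
screen — at some cost in power for weakly coupled pairs. Users who need
exact sizing should calibrate $D$ by simulation on their own tree; the
package's forward simulator makes that a few lines.

## Gain/loss coefficient summary

Fitting the single-trait model to every GCF column and taking the ratio
$r = q_{01}/q_{10}$ gives the package's gain/loss summary. Individual
ratios are very noisy (a single binary character barely identifies two
rates, and boundary fits produce extreme outliers), so the reported
quantities are the **median** and the plain median absolute deviation
over converged, non-degenerate, informative traits. In simulations at
ratio 0.016 the median over ~100 informative traits recovered
0.016-0.02; per-trait estimates scatter over orders of magnitude and
should not be interpreted individually.

## The chi-squared comparator

The phylogeny-ignorant screen builds, per pair, the 2x2 contingency
table of presence/absence over strains and applies the Pearson statistic
with Yates continuity correction (the convention of standard 2x2
implementations; verified against `chisq.test`). Because RQ filters the
phylogeny-aware screen to positive associations, the comparator applies
the analogous direction filter (observed co-presence above expectation)
so the two methods predict the same kind of object. Both run at
$\alpha = 0.01$ for comparability; the comparator's threshold is a
package interpretation, as the original decision rule was only stated
for the phylogeny-aware test.

## BGC curation

The curation stage prepares GCF presence matrices from gene tables
(antiSMASH-region-like: ordered genes with categories and domain
labels).

* **Supercluster splitting.** Prediction tools can fuse adjacent
  clusters into one over-long region. Within each family, a member
  region is split when its core genes partition into groups such that a
  *shorter region from another genome* matches exactly one group
  (cross-strain evidence), every group keeps at least one core gene, and
  every cut lies in a gap free of core genes. Children inherit
  interleaved non-core genes up to the cut (placed at the midpoint of
  the non-core run); the gene multiset is conserved exactly and every
  split is logged with its evidence regions. Gap tolerance
  (`gap_genes = 2`) and the one-core-per-child minimum are configurable;
  they are engineering defaults chosen so that a fused two-to-three-
  cluster region with single-cluster partners splits, since the original
  curation was manual and published no thresholds.
* **Core-gene reduction.** After splitting, regions are reduced to their
  core biosynthetic genes, deliberately ignoring accessory content and
  imprecise boundaries; regions with no core gene are excluded and
  logged.
* **Family clustering.** The pairwise region distance is
  $d = 1 - (0.7\,J_{dom} + 0.3\,J_{adj})$, where $J_{dom}$ is the
  Jaccard similarity of domain-family sets and $J_{adj}$ of domain
  bigram sets (adjacency); families are single-linkage components at
  $d \le 0.4$. This is a deliberately simple, declared stand-in for
  external BGC clustering tools (BiG-SCAPE-like), adequate for
  synthetic-data pipelines and tests: it shares the qualitative
  behaviour (identical regions at $d = 0$, disjoint content at $d = 1$,
  family counts non-increasing in the cutoff) but not the alignment
  machinery. Real studies should cluster with the external tool and feed
  the resulting matrix in directly. Note one structural consequence: the
  Jaccard term caps the similarity between a $K$-block fusion and a
  single-block region at $1/K$, so the grouping pass that *detects*
  superclusters uses a permissive cutoff (the fixture generator records
  0.8), while the final clustering after core reduction uses 0.4.

## MF presence calling

An MF is present in a strain iff at least 3% of the MF's features are
detected there *and* at least one detected feature carries the
protonated-molecule adduct `[M+H]+` (evidence the compound itself, not
only a fragment or adduct artifact, was seen). The fraction comparison
is integer-exact, so the boundary (exactly 3%) is reproducible. A
feature counts as detected when seen in any replicate (configurable to
majority); distinct features, not feature x adduct combinations, are
counted (configurable). Adduct labels are whitespace-stripped and can be
mapped through a synonym table.

## Richness rarefaction

Incidence-based (sample-based) rarefaction of GCF richness uses the
hypergeometric expectation
$S(t) = S_{obs} - \sum_i \binom{T-Y_i}{t} / \binom{T}{t}$ and
extrapolation beyond the observed $T$ strains approaches the Chao2
asymptote $S_{obs} + \frac{T-1}{T} \frac{Q_1^2}{2 Q_2}$ (bias-corrected
form when $Q_2 = 0$) geometrically. Only richness (Hill order 0) is
implemented, matching the analysis this package supports;
class-stratified curves are obtained by filtering columns.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every statistical guarantee in the test suite is
stated.

* **Tree**: Yule (pure birth) with the study-scale 72 tips, rescaled to
  unit mean root-to-tip depth.
* **Background traits**: independent two-state chains at gain/loss ratio
  0.016 (loss rate 1 per unit depth), root drawn from the stationary
  law. This reproduces the sparse incidence structure of real BGC
  matrices (expected carrier fraction $\approx 0.016/1.016 \approx
  1.6\%$) and the regime in which most traits are ineligible for the
  pair test.
* **Linked pairs**: simulated under the dependent model with a single
  coupling factor $\kappa$ (default 8) that multiplies gain-with-partner
  and divides loss-with-partner rates, from base rates
  $q_{01} = 0.6, q_{10} = 3$ and an ancestrally absent root. These
  defaults emulate the proof-of-principle known pairs of real datasets:
  traits gained and lost repeatedly across the tree (~8 parsimony
  changes per trait, prevalence ~0.4), which is precisely the regime the
  method needs — with near-fixed or single-clade traits the pair test is
  starved of events regardless of the true coupling. Each linked pair is
  resimulated (bounded retries) until both traits show at least two
  parsimony changes *after* MF dropout, so planted truth always passes
  the eligibility filter.
* **MF dropout**: each MF presence is deleted with probability 0.1,
  modelling condition-dependent non-production under a single culturing
  condition.
* **Curation fixtures**: gene tables with planted fused superclusters
  (2-3 core blocks), single-block partner genomes and distractor
  regions; the expected split log is emitted as ground truth.
* **Feature tables**: detection records consistent with a given MF
  matrix (present strains get above-threshold detections including an
  `[M+H]+` feature; absent strains sub-threshold or adduct-less ones),
  for round-trip tests of the presence caller.

What the generator does *not* emulate: measurement error on the tree,
horizontal transfer as a distinct process (gains are i.i.d. along
branches), chemically structured MF-GCF mismatches (an MF produced by
two unrelated pathways), or intensity-dependent MS detection. Passing
tests on synthetic data therefore demonstrate correctness of the
machinery under the stated model, not robustness to violations of it.

## Problem sizes used by the test suite

The acceptance checks run at sizes chosen to finish quickly while
keeping the statistical assertions meaningful: brute-force likelihood
comparisons on trees of up to 6 tips (exhaustive enumeration); null
calibration over 2000 independent pairs on 24-tip trees; power over 100
planted pairs on a 72-tip tree; rate-ratio recovery over 100 informative
traits; supercluster recovery over 50 randomized fixtures; permutation
controls with 20 shuffles on a 40-strain dataset. The acceptance script
reruns the full study-scale pipeline (72 x 265 x 99 with 9 planted
pairs) end to end.

## Known limitations

* The chi-squared reference for the LRT is conservative at small tree
  sizes (see above); exact sizing requires simulation-based calibration.
* Per-trait rate ratios are weakly identified; only their median over
  many traits is a stable summary.
* The clustering stand-in is not a substitute for a real BGC clustering
  tool on real data.
* Eligibility uses parsimony change counts, which undercount events on
  long branches.
* The pair model assumes no simultaneous dual transitions and
  homogeneous rates across the tree.
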