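---
title: "Designing combination therapies from ex vivo drug-response screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing combination therapies from ex vivo drug-response screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combnet)
```

## The problem and the model

Acute myeloid leukemia responds poorly to monotherapy, and exhaustive
two-drug screening on patient material is infeasible: the cells available
from a bone-marrow aspirate limit a screen to a few dozen wells, while the
combination space of even a modest drug library has tens of thousands of
pairs. `combnet` implements a network strategy that uses *single-agent*
ex vivo screening data on patient and healthy-donor samples to nominate a
short list of combinations worth measuring.

The input is a sample-by-drug matrix of cell-death readouts. After
restriction to a complete (no-missing) submatrix, readouts are min–max
normalized to inhibition rates

$$R_{\mathrm{inhibition}} = \frac{x - \min x}{\max x - \min x} \in [0, 1],$$

so 1 is the highest observed sensitivity. The normalized matrix $A$ defines
a weighted bipartite network $G = (V_1, V_2, E, \omega)$ with samples on one
side, drugs on the other, and $\omega(s_i, d_j) = a_{ij}$. Projecting onto
the drug side gives a drug similarity network with weights

$$w_{ij} = \sum_k a_{ik}\, a_{jk},$$

the off-diagonal of the Gram matrix $A^\top A$: two drugs are similar when
they inhibit the same samples strongly. Only edges strictly above the median
similarity are kept, and weighted Louvain modularity maximization partitions
the drugs into communities of pharmacologically similar compounds. Drugs
from *different* communities kill through different sample-level
vulnerabilities, which is the rationale for combining across communities.

Two read-only corroboration analyses check that detected communities are
biologically coherent. First, each protein target $P$ is scored by
$S(P) = \log(f_{1,P}/f_{2,P})$, the log-ratio of distinct drugs targeting it
in the two clusters; proteins with $S > \log 2$ (strictly) form the
preferentially targeted set PPT1 and $S < \log 0.5$ forms PPT2, and
cluster-exclusive sets G1/G2 collect proteins hit by at least three drugs of
one cluster and at most two of the other. Enrichment of such sets against
user-supplied annotations uses the upper-tail hypergeometric test with
Benjamini–Hochberg FDR and fold enrichment $(k/n)/(K/N)$. Second, chemical
homogeneity is tested on fingerprint Dice similarities
$S_{A,B} = 2c/(a+b)$: intra-cluster pairs should be more similar than
inter-cluster pairs (one-sided Welch $t$ and Wilcoxon rank-sum tests).

Candidate drugs are ranked on two coordinates: *efficacy*, the mean
normalized inhibition over patient samples, and *toxicity*, the same mean
over healthy samples. Drugs strictly better than the screen average on both
coordinates are ranked by efficacy minus toxicity; the top 5% (capped at
four drugs per cluster) enter combination testing. Pairs are labeled
inter-cluster or intra-cluster, and the design's key claim — inter-cluster
pairs co-optimize efficacy and toxicity — is tested with a one-sided exact
binomial proportion test: a pair is a success when its efficacy exceeds the
third quartile of all pairs *and* its toxicity falls below the first
quartile, and the success proportion among inter-cluster pairs is compared
with a null probability of 0.33.

Measured (or simulated) dose–response surfaces are scored against four
synergy null models, each producing a per-cell excess (observed minus
expected inhibition fraction) summarized as $100 \times$ mean excess:

* **HSA** — expected effect is the better single agent,
  $\max(y_a, y_b)$;
* **Bliss** — probabilistic independence, $y_a + y_b - y_a y_b$;
* **Loewe** — dose additivity: the $y$ solving
  $x_a / D_a(y) + x_b / D_b(y) = 1$, where $D(\cdot)$ inverts a fitted
  four-parameter Hill curve
  $y(x) = e_{\min} + (e_{\max}-e_{\min})/(1 + (\mathrm{EC}_{50}/x)^h)$;
* **ZIP** — a Bliss-form expectation computed from the fitted (not raw)
  monotherapy curves, with the observed surface smoothed by conditional Hill
  refits along each dose axis and the two deltas averaged.

The combination ratio $\mathrm{CR} = y_{ab} / \max(y_a, y_b)$ flags added
benefit when above 1, and a simplified drug-sensitivity score (DSS)
summarizes a monotherapy curve as the normalized area above a 10% activity
threshold on the log10-dose axis.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| normalization scope | `global` | one min–max over the whole matrix ("a uniform measure"); `per_drug` rescales each column |
| median filter | strict `>` | edges equal to the median are dropped; even counts use the midpoint of the central order statistics |
| Louvain `resolution`, `seed` | 1.0, 0 | community count is *not* forced to two; the partition is whatever modularity maximization yields under the fixed seed |
| PPT threshold | `log(2)` | natural log; membership is base-invariant because the threshold and score share the base |
| G-set rule | `min_in = 3`, `max_out = 2` | cluster-exclusive protein sets |
| selection | `fraction = 0.05`, `per_cluster = 4` | overall cap `ceiling(fraction * n_drugs)` applied first, then the per-cluster cap |
| proportion test | `p0 = 0.33`, exact binomial | quartiles are type-7 (linear interpolation), computed once over the pooled pair set |
| dose ladder | 1, 10, 100, 1000, 10000 nM | five-point design used for combination surfaces |
| DSS threshold | 0.10 | activity floor on the inhibition-fraction scale |

Several of these resolve questions the method's description leaves open; the
choices are documented here rather than buried in code. The natural
logarithm is used for $S(P)$; strictness at the PPT boundary means a protein
with $f_1/f_2$ exactly 2 is excluded; proteins targeted by one cluster only
receive infinite sentinel scores and land in the corresponding PPT set (a
pseudocount policy is available). The ranking rule inside the top-5% filter
(efficacy minus toxicity, ties by drug id) is a package choice: the
selection quadrant is defined by the mean filters, but an order within it is
needed for the caps to be deterministic.

## What the synthetic screen emulates

`simulate_screen()` generates the whole study's input with known ground
truth. Patient samples alternate between two response subtypes; cluster-1
drugs inhibit subtype-1 samples above the mid-scale baseline and subtype-2
samples below it, cluster-2 drugs the mirror image. The per-sample profile
gap is `profile_separation` noise standard deviations, so separation is an
effect size. Each drug also carries a potency offset
($\mathcal{N}(0, \sigma/2)$) so drugs within a cluster differ in overall
activity, and healthy-sample responses are the drug's patient-level mean
scaled by `healthy_attenuation`, realizing the efficacy/toxicity geometry
with one knob. All responses are truncated to $[0, 1]$.

`noise_sd` defaults to 0.1: replicate noise of about ten percent of the
inhibition scale is typical of ex vivo viability screens, and at the default
separation of six the planted profiles then span roughly 0.2–0.8, the
dynamic range real active/inactive compounds occupy. This matters because
the product projection $\sum_k a_{ik} a_{jk}$ carries a baseline term of
order $0.25$ per sample; a planted contrast much smaller than that baseline
would be an unrealistically faint clustering signal.

Missingness defaults to a *structured* mechanism: drugs are grouped into
assay panels and whole sample-by-panel blocks are untested, with the block
count fixed so the realized missing-cell density equals `missing_rate`
exactly. This is how screening data actually go missing — a sample is run
against a panel or not at all — and it is the only mechanism consistent
with the kind of dataset the generator emulates, where roughly 40% of
samples and half the drugs survive into a complete submatrix. Under
independent per-cell missingness at rate 0.2 the maximal complete submatrix
of a 50-by-40 screen is only about 13-by-13 (~180 cells), a geometry no real
screen produces; an `"iid"` option retains that mechanism for stress
testing. The generator does not emulate plate effects, dose-level
variation within the single-agent screen, cell subpopulations, or
mutation structure, so passing tests say nothing about robustness to those
features of real data.

`simulate_target_map()` draws each drug's targets from its own cluster's
protein pool with probability `bias` (0.5 = no preference, 1 = exclusive
pools). `simulate_fingerprints()` gives each cluster a seed fingerprint and
derives members as independent bit-flipped copies, with the flip probability
solved numerically so the expected intra-cluster Dice equals
`within_similarity`; because a flip probability of one half fully
randomizes a copy, expected similarities at or below 0.5 are unreachable by
this construction and are rejected. Inter-cluster similarity concentrates
near the bit density (default 0.5). `simulate_surface()` evaluates two Hill
curves on the dose ladder and fills combination cells with a chosen null
model's expectation (`bliss_independent`, `hsa_max`, `sham_self` for
dose-additivity of a drug with itself, or `additive_shift` for the general
Loewe expectation) plus an interaction offset `shift_delta`, so every
synergy model can be validated against a surface whose true excess is known.

## Numerical choices

* Loewe inversion is by bisection on the response, iterated to an interval
  below $10^{-9}$ (well past the documented $10^{-6}$ tolerance); when even
  the largest jointly achievable response leaves the dose sum above one, the
  expectation is clamped to $\min(e_{\max,a}, e_{\max,b})$ and the cell is
  flagged and counted.
* Hill fitting is bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  box constraints ($e_{\min}, e_{\max} \in [0,1]$, EC50 within two decades
  of the dose range, slope in $[0.1, 10]$) and an `optim` L-BFGS-B fallback;
  a dynamic range below 0.01 is flagged degenerate rather than fatal. With
  five doses a shallow curve's $e_{\max}$ is weakly identified, which is an
  inherent limit of the five-point design, not of the optimizer; the
  sham-combination identity test uses curves the grid pins down.
* The ZIP implementation approximates the full two-way potency-shift fit by
  conditional four-parameter refits along each axis, averaged; a stratum
  whose refit fails falls back to the raw observations.
* Degenerate homogeneity inputs (all similarities identical) report p = 1
  with a zero-variance flag instead of erroring.
* Community ids are relabeled to be contiguous from 1; Louvain tie-breaking
  is delegated to the seeded RNG, making partitions reproducible
  bit-for-bit under a fixed seed.
* The complete-submatrix extractor is a greedy heuristic (delete the worst
  row or column, preferring the deletion that keeps the most observed cells)
  followed by a restoration pass, so its output is always *maximal* — no
  deleted line can be re-added — though not guaranteed optimal; on
  exhaustively enumerable 8-by-8 instances it stays within 80% of the true
  optimum in the package's tests.

## Scope of the validation suite

The test suite validates each stage against independent oracles (dense
matrix products, enumeration sums with `choose()`, exhaustive partition
search for modularity on six nodes, brute-force submatrix enumeration on
8-by-8 masks) and runs the full pipeline on planted screens at 40 patients,
10 healthy donors and 20+20 drugs with 20% structured missingness, 20
replicates; larger end-to-end checks use up to 120 samples and 300 drugs.
These sizes keep the suite fast while exercising every code path at the
screen geometry the method targets; behavior at 10-fold larger screens is
a matter of linear algebra and Louvain scaling, not of different code.

## Known limitations

* Pairwise Dice similarities share drugs and are therefore dependent; both
  the $t$ and Wilcoxon homogeneity tests ignore this. The package's tests
  include a label-shuffling calibration showing the joint rejection rule
  holds its nominal level on exchangeable fingerprints, and that
  permutation check is the honest alternative on real data.
* The proportion test's null probability 0.33 is a convention inherited
  with the design; it is exposed as a parameter, and the exact binomial
  mode is the default because the inter-cluster pair count is small.
* When only screen data are available, a combination's efficacy/toxicity is
  proxied by the per-sample Bliss composite of the two drugs' single-agent
  responses; this is a modeling convenience for synthetic end-to-end runs,
  not a substitute for measured combination responses.
* Exact numeric parity with web-service synergy implementations is not a
  goal; the reference models are implemented from their definitions and
  validated against constructed surfaces with known excess.
* Fingerprint generation from chemical structures is out of scope; the
  similarity machinery consumes abstract bit sets from any source.
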