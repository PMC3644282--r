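---
title: "Learning gene-set interaction networks with condition-specific edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning gene-set interaction networks with condition-specific edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxnet)
```

## The problem

Tumour collections are heterogeneous: a dependency between two functional
modules may hold only in melanoma samples, or only in one glioblastoma
subtype, and be invisible — or misattributed — when a single network is fit
to all samples. `ctxnet` learns an interaction network over *gene sets*
(coherent transcriptional modules used as single variables) and then asks,
for every interaction and every sample condition, whether the condition's
samples are what created it.

The pipeline has four stages:

1. **Quantization.** Expression is reduced to three states, `UP`, `DOWN`,
   `NOCHANGE`, either by fold change against a matched baseline (default
   two-fold, boundary inclusive) or by z-score against reference samples
   (default one standard deviation, boundary exclusive). The two boundary
   conventions are deliberate, fixed choices so that results are exactly
   reproducible; the underlying thresholds are conventional in tumour
   profiling.
2. **Summarization.** Each gene set $\mathbf{G}_i$ becomes one variable:
   its value in sample $k$ is `UP` when *strictly more than* a fraction
   $r$ (default 0.5) of its member genes are `UP` **and** the
   hypergeometric upper-tail probability of drawing that many `UP` members
   from the quantized background is below a threshold (default 0.05);
   symmetrically for `DOWN`; otherwise `NOCHANGE`. Both clauses are
   conjunctive: an insignificant majority summarizes to `NOCHANGE`. The
   hypergeometric background universe is all genes present in the input
   matrix — the only universe the program can know.
3. **Consensus network.** The dependency likelihood of a pair,
   $d_{ij} = \Pr(\mathbf{G}_i \leftrightarrow \mathbf{G}_j \mid S_U)$, is
   estimated as the fraction of $R$ independent stochastic structure
   searches whose learned Bayesian network contains an edge between $i$
   and $j$ *in either direction* (direction is ignored throughout). An
   interaction is called when $d_{ij} > d_\theta$, strictly (defaults:
   $R = 1024$, $d_\theta = 0.5$).
4. **Condition specificity.** For a condition $T_k$ with samples
   $S_{T_k}$, the condition-effect ratio is
   $$\gamma(\mathbf{G}_i \leftrightarrow \mathbf{G}_j; S_U, S_{T_k}) =
     \frac{d_{ij}}{d_{ij}^{T_k}},$$
   where $d_{ij}^{T_k}$ is recomputed from $S_U - S_{T_k}$. Under sample
   exchangeability and a uniform structure prior, $\gamma$ is proportional
   to $\Pr(\mathbf{G}_i \leftrightarrow \mathbf{G}_j \mid S_{T_k})$, the
   direct — but small-sample-starved — measure of the edge's support in
   the condition, which is why the leave-out form is used. Significance
   comes from a permutation null: $M$ random sample subsets of size
   $|S_{T_k}|$ are left out in turn, and $p = H/M$ exactly, where $H$
   counts permutations whose ratio meets or exceeds the observed one (ties
   count). An edge is *specific* to $T_k$ when $\gamma > \gamma_\theta$
   and $p < p_\theta$ (defaults 2 and 0.05). Gene sets whose called edges
   are all specific to one condition are *centric* to it; sets with no
   specific edge are *generic*; the rest are *mixed*.

## The structure search and its score

Each of the $R$ runs is a greedy hill climb over add / delete / reverse
edge moves, scored by the BDeu marginal likelihood (Dirichlet prior of
total mass `ess`, default 1, spread uniformly), with at most
`max_parents` (default 5) parents per node. Runs differ only in their
seeded random starting DAG — a uniformly random topological order with
each forward edge included with probability $\min(2/(n-1), 1/2)$ — which
is precisely what makes the edge frequency across runs informative: a
dependency that every local optimum contains gets $d \approx 1$; one that
only a lucky start retains gets an intermediate frequency.

Numerical conventions, all deterministic given the seed:

* Only strictly improving moves are taken. A score tie between adding an
  edge and not adding it resolves to *not* adding (prefer sparsity); equal
  best moves resolve by a fixed lexicographic move order.
* Variables constant across all samples carry no information for the
  discrete score; they are excluded from search and reported with $d = 0$
  to every partner.
* Per-run seeds derive from the configuration's base seed and the run
  index through a 64-bit splitmix mixing function, so disjoint run blocks
  (and the permutation test's many sub-consensus calls) never share
  search trajectories. A cryptographic fold would serve equally; the
  mixing function was chosen to keep the compiled core dependency-free.
* When $d^{T_k}_{ij} = 0$, $\gamma$ would be undefined; the denominator is
  floored at $1/(R+1)$ — one pseudo-count at the frequency resolution —
  so ratios stay finite and permutation comparisons well defined.
* $p = H/M$ is reported exactly as defined (zero p-values are possible);
  no smoothing, and no multiple-testing correction across (edge,
  condition) pairs by default, matching the raw-threshold convention of
  the method. `test_all(..., bh = TRUE)` reports Benjamini–Hochberg
  adjusted p-values as an opt-in extra column.

One design deviation is worth recording: permutation subsets are drawn
once per *condition* and shared across edges, rather than re-drawn per
(edge, condition) pair. Marginally, each edge still faces $M$ uniformly
drawn subsets of the right size, so each single test is unchanged; the
sharing makes a single-edge `specificity_test()` and the batch
`test_all()` agree exactly for the same seed, and reduces the dominant
cost ($M \times R_\mathrm{perm}$ structure searches) by a factor of the
edge count. `R_perm` is independently configurable from `R` because those
permutation consensuses dominate the runtime.

## The boolean-network validation

The packaged validation experiment simulates the cholesterol regulatory
pathway — synthesis from acetyl-CoA through mevalonate to cholesterol,
statins inhibiting HMG-CoA reductase, and cholesterol feeding back on
SREBP-SCAP — as a synchronous boolean network
(`cholesterol_network()`), generates 100 attractor samples per arm with
statins clamped off/on, runs the full pipeline, and asks which pathway
regulations are specific to the statins perturbation. The expected
answer, which `tests/testthat/test-acceptance.R` asserts, is that exactly
the two regulations on the statins path — statins ⊣ HMG-CoA reductase and
HMG-CoA reductase → mevalonic acid — come out specific, while every
downstream synthesis step, whose value is fixed once mevalonate is given,
does not.

Sampling protocol: per sample a uniformly random initial state is drawn,
clamps applied, and the network iterated synchronously until a state
revisits (attractor); fixed points emit themselves, cycles emit one
uniformly chosen state. Boolean states map 1 → `UP`, 0 → `DOWN` so the
simulated data flows through the standard pipeline unchanged.

The model file (`inst/extdata/cholesterol.bn`) is data, not code: one
line per node, `node = EXPR` over AND/OR/NOT. Its reconstruction follows
the published pathway logic — every multi-input junction is an AND except
cholesterol, an OR over its two terminal synthesis branches
(desmosterol / 7-dehydrocholesterol); inhibitions are NOTs — plus three
modelling choices that matter and deserve justification:

* **Cofactor inputs.** The reductase step consumes NADPH and the
  mevalonate kinase step consumes ATP; both appear as persistent input
  nodes. Beyond fidelity, they break the perfect collinearity a chain of
  pure copy reactions would otherwise have at steady state, which would
  make the learned position of chain edges arbitrary.
* **Persistent SREBP-SCAP activation.** The activated SREBP pool, once
  released by cholesterol depletion, stays active at the sampling
  timescale (a self-OR: activation with hysteresis). Without some damping
  of the negative feedback loop, the free-running system has *no* fixed
  point with active synthesis — its synchronous dynamics are an
  invertible travelling wave whose sampled cycle states are uncorrelated
  across nodes, erasing the very regulations the experiment is supposed
  to recover. With hysteresis, both arms settle into rule-consistent
  fixed points: with statins the whole mevalonate branch is off in every
  sample regardless of HMG-CoA; without statins the reductase is
  constitutively active and synthesis tracks the metabolic inputs.
* **Input-state variability.** Metabolic inputs (acetyl-CoA, NADPH, ATP)
  hold their random initial state, standing in for sample-to-sample
  metabolic variation; this is what gives the statin-free arm informative
  variance.

What passing this experiment shows — and what it does not: the simulated
data is noise-free, its dependencies are deterministic, and both arms are
balanced. Success demonstrates that the leave-condition-out ratio
separates condition-driven from condition-indifferent dependencies under
clean conditions; it says nothing about measurement noise, unbalanced
conditions, or the context-mining step that produces gene sets from real
expression data (outside this package's scope — gene sets arrive as GMT
input).

## The synthetic planted-dependency generator

`generate_planted()` emulates summarized gene-set matrices: background
variables i.i.d. over the three states (default marginals 0.25 / 0.50 /
0.25 for DOWN / NOCHANGE / UP — symmetric, with change states together as
frequent as no-change, roughly matching two-fold-quantized tumour
profiles), condition blocks over the samples, and planted edges where one
variable copies another with probability `strength` inside a condition
block and is independent elsewhere, followed by entry-wise replacement
noise. The generator returns the ground truth for scoring.

A detection-limit property of the BDeu score is worth knowing when
choosing designs: one extra trinary parent costs about 10 nats at
$n = 200$, while a strength-0.9 copy confined to a quarter of the samples
contributes only 3–6 nats of fit, so such an edge is — correctly, from
the score's point of view — mostly *not* called from the full data (its
recovery rate is a property the acceptance suite measures rather than
assumes). A dependency spanning half the samples is comfortably above the
limit and is the regime the recovery and calibration tests use.

The rank-consistency experiment (the testable content of the
proportionality between $\gamma$ and the condition-only edge frequency)
uses eight designs with strengths 0.15–0.50, a 150-of-200-sample
condition block, and twenty replicates per design; $\gamma$ is aggregated
by median (robust to the occasional chance association in the small
leave-out complement) and the condition-only frequency by mean. Problem
sizes throughout the test suite (10–20 variables, 100–200 samples,
$R$ = 64–256, $M$ = 40–100) were chosen so each experiment's Monte-Carlo
error is small relative to what it asserts.

## Known limitations

* The structure search is greedy hill climbing; $d_{ij}$ is a frequency
  over local optima, not a posterior edge probability. An exact
  enumeration oracle is used in the tests at two variables, where the two
  coincide as an indicator.
* Identical (perfectly collinear) variables make edge placement among
  them arbitrary up to score ties; the consensus then spreads $d$ across
  the equivalent pairs. This is inherent to score-based learning, not an
  implementation artefact.
* The permutation p-value has resolution $1/M$; with the default
  $M = 100$, the smallest nonzero p is 0.01.
* Conditions may overlap and are tested independently; no partitioning of
  samples is assumed, and no correction is made across conditions by
  default.
* The fold-change quantizer expects strictly positive ratio data;
  z-score quantization needs at least two reference samples and flags
  zero-variance genes rather than guessing.
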