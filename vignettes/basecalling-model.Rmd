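---
title: "Model-based base calling on a 16-state trellis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based base calling on a 16-state trellis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sequencing-by-synthesis instruments read a DNA template one chemistry cycle
at a time: in cycle $i$ every strand of a clonal cluster should incorporate
one fluorescently labeled terminator complementary to template position $i$,
and imaging yields a 4-vector of channel intensities $Y_i$ per cluster.
Base calling infers the template sequence $S_1, \dots, S_N$ from
$Y_1, \dots, Y_N$. The signal is corrupted by several well-characterized
physical effects:

* **Crosstalk** ($K$, $4 \times 4$): the four fluorophore emission spectra
  overlap, linearly mixing the channels.
* **Phasing / pre-phasing** ($p_{ii}$, $p_{cf}$): a strand may fail to
  extend in a cycle, or extend by two bases, so the cluster population
  de-synchronizes and the cycle-$i$ signal leaks into neighboring template
  positions.
* **Droop** ($\bar d_j$): cumulative loss of active strands attenuates the
  signal multiplicatively each cycle.
* **Leakage** ($\alpha$): a fraction of the previous cycle's measured
  signal carries into the current measurement.
* **Per-read scale** ($\lambda$): cluster brightness varies from read to
  read (and decays stochastically along the read).
* **Multiplicative noise** ($\Sigma$): measurement noise whose scale is
  proportional to the signal magnitude, $\mathrm{cov}(Y_i) =
  \lVert X_i \rVert^2 \Sigma$.

`softcall` implements a generative model of all of these, an exact posterior
decoder, a fast approximate decoder, and an online unsupervised estimator of
every parameter — plus a simulator so the whole stack can be validated
without instrument data.

## Generative model (the simulator)

Phasing is a Markov chain on strand length: from length $i$ a strand stays
with probability $p_{ii}$, extends by one with $(1-p_{ii})(1-p_{cf})$ and by
two with $p_{cf}(1-p_{ii})$. Collecting these in a transition matrix $P$,
the probability that a strand has length $j$ after $i$ cycles is
$E_{ij} = [P^i]_{0j}$, and the noiseless unit-scale signal at cycle $i$ is
$\sum_j E_{ij}\, S_j$ with $S_j$ the one-hot column of template base $j$
(only the most recently incorporated base fluoresces). The observed
intensity is

$$
Y_i \mid Y_{i-1} \sim \mathcal N\!\big(K X_i + \alpha Y_{i-1},\;
  \lVert X_i \rVert^2 \Sigma\big), \qquad
X_i = \lambda_i \textstyle\sum_j E_{ij} S_j ,
$$

with the leakage term absent at $i = 1$, and the per-cycle scale following
a decaying autoregression
$\lambda_i \mid \lambda_{i-1} \sim \mathcal N\big((1-d)\lambda_{i-1},
(1-d)^2 \lambda_{i-1}^2 \sigma_\lambda^2\big)$.

`simulate_tile()` draws templates of length $N + 10$ so phasing mass cannot
run off the template end within the $N$ observed cycles, generates every
read from one tile-seeded RNG stream (fixed seed, byte-identical files),
writes the intensity TSV dialect and a truth FASTA, and floors $\lambda$
trajectories at $10^{-6}$ (the Gaussian step can in principle cross zero;
at realistic volatilities the floor is never reached).

**What the defaults emulate.** The default configuration (250 reads,
36 cycles, $p_{ii}=0.002$, $p_{cf}=0.01$, $d=0.03$, $\alpha=0.05$,
$\sigma_\lambda=0.05$, diagonally dominant $K$ with within-pair spectral
overlap, $\Sigma = 0.15^2 I$) was chosen once to produce overall error
rates between a few tenths of a percent and a couple of percent over
36 cycles — the magnitude real lanes of this platform class exhibit — with
phasing-driven growth toward late cycles. What the simulator does **not**
emulate: spatial tile effects, cluster-image artifacts, optical duplicates,
template-sequence-dependent chemistry (GC effects), or indels. Passing
simulation tests therefore demonstrates correctness of the inference
machinery under the stated model and its phasing mismatch (below), not
performance on any particular instrument run.

## Decoding model (the two-term approximation)

The full dependence of $X_i$ on the whole template prevents efficient exact
decoding. Because $p_{ii}$ is small and at most one lookahead base carries
non-negligible phasing mass at practical cycle counts, the decoder keeps
two terms only:

$$
X_i \approx (1 - \beta_i)\, S_i + \beta_i\, S_{i+1},
$$

with a per-window mixing weight $\beta_i$ absorbing the nonlinear
dependence on $p_{cf}$. The emission used by the decoder (for window $l$,
with cumulative droop $D_i = \prod_{j=2}^{i}(1-\bar d_j)$) is

$$
Y_i \mid Y_{i-1} \sim \mathcal N\!\big(\lambda D_i K X_i + \alpha Y_{i-1},\;
 (\lambda D_i)^2 \lVert X_i\rVert^2 \Sigma \big).
$$

The simulator deliberately uses the full profile while the decoder uses
the two-term approximation, reproducing the model mismatch a real
instrument presents.

Since $X_i$ depends on $(S_i, S_{i+1})$, decoding is dynamic programming on
a 16-state trellis whose stage-$i$ states are ordered base pairs; a
transition is valid iff the states overlap in the shared position. Two
decoders are provided:

* `forward_backward()` computes exact per-stage state posteriors (and base
  posteriors by summing the four states sharing a first symbol) in the log
  domain.
* `sova()` runs Viterbi and scores, for every position and alternative
  base, the best path that deviates from the optimal one by at most 3
  trellis edges. Changing the base at position $i$ forces the states at
  stages $i-1$ and $i$ to change, which is exactly a 3-edge deviation, so
  the competitor per alternative base is unique and available in closed
  form from local emission swaps. The four path metrics are normalized by
  a softmax into approximate posteriors. The softmax rule is this
  package's documented choice — the classical soft-output Viterbi
  literature specifies competitor metrics but not a unique normalization —
  and is validated against exact forward–backward posteriors (rank
  correlation above 0.98 in the shipped tests).

### Numerical and boundary choices

* All recursions and densities are computed in natural-log space with
  log-sum-exp reductions; 100-cycle reads underflow linear-domain
  arithmetic.
* **Terminal stage**: the backward recursion is initialized with a
  constant end-state weight ($b_k(M) = \text{const}$), i.e. a virtual end
  state reachable equally from all 16 states. This is the unique choice
  under which trellis posteriors equal brute-force marginalization of the
  joint likelihood, which the test suite asserts to $10^{-8}$ on
  enumerable instances. Weighting terminal states by their forward
  probabilities instead (a reading the original soft-output literature
  permits) would square the last stage's forward mass and break that
  equality.
* **Initial stage**: uniform over the 16 states unless per-position priors
  are supplied; with priors, the stage-1 prior is the product
  $\pi_1(b_1)\pi_2(b_2)$ and transitions into stage $i+1$ are weighted by
  $\pi_{i+2}$ (the product rule for pair states).
* **Ties** in Viterbi backtracking go to the lowest state index —
  deterministic and stable.
* **Windows and padding**: each window decode appends 5 extra cycles of
  observations (truncated at the read end; observations are never
  fabricated) so the finite trellis horizon does not perturb within-window
  posteriors; at the shipped noise levels the truncation error is below
  $10^{-3}$ total variation (tested) and typically orders of magnitude
  smaller.
* The final template position has no successor, so its posterior comes
  from the last stage's second-symbol marginal; equivalently $\beta$ at
  the template end is irrelevant because pad cycles cover every reported
  position.

## Parameter estimation (windowed online EM)

Parameters $\Theta = \{\alpha, \beta, K, \Sigma, \bar d_j\}$ drift along a
run, so the run is split into windows of $W = 6$ cycles, estimated in
order; window $l$ is initialized from window $l-1$ and, to prevent
over-fitting, optimized over the span of windows $l$ and $l+1$ (the result
is assigned to window $l$; a final partial window is merged into its
predecessor). Training uses $R = 250$ reads drawn uniformly from the tile.

**Initialization (window 1).** Crosstalk columns are estimated from the
first two cycles by max-channel calls and column-wise medians with five
refine iterations (invert, re-call, re-estimate; the column mean is added
to the diagonal before each inversion as regularization). The base
covariance comes from first-two-cycle residuals against the called
crosstalk column, aggregated by elementwise medians; because the median of
a two-sample second moment is biased low by the median of a
$\chi^2_2/2$ variate, the estimate is rescaled by $1/\ln 2$. Per-cycle
droop factors come from median ratios of consecutive total corrected
signals — the ratio is a retention factor, stored as droop
$1 - \text{retention}$ so it enters the model as $(1-\bar d_j)$. $\alpha$
and $\beta$ start at zero (negligible in early cycles). Intensities are
pre-scaled so the tile-median initial scale is 1 (the scale model has no
natural units; the factor is recorded in the fit and applied transparently
when calling).

**E-step, window 1.** Sequence hypotheses come from the baseline caller
(below). The expectation over the per-read scale $\lambda^k$ is evaluated
by self-normalized importance sampling: $N_{IS} = 500$ draws per read from
$\mathcal N(\hat\lambda^k, 0.1)$, weighted by the window likelihood over
the proposal density. The distribution parameter 0.1 is read as a
*variance* (the convention is ambiguous in the soft-output base-calling
literature) and is exposed as `proposal_var`; self-normalized weights make
the estimator insensitive to this reading. Because the window
log-likelihood depends on $\lambda$ only through $\log\lambda$,
$1/\lambda$ and $1/\lambda^2$, the weighted objective reduces to three
moments per read, which is what the implementation stores.

**E-step, later windows.** $\lambda^k$ is fixed at its current estimate
and the sequence expectation is taken under per-cycle base posteriors from
trellis decoding (forward–backward by default; SOVA optionally) at the
current parameters. Each (read, cycle) contributes four weighted
hypotheses $S_i = s_j$; the lookahead slot $S_{i+1}$ in $X_i$ is filled
with the current hard call — the weighting as printed marginalizes the
current position only, and completing the pair with the decoded call is
this package's documented resolution.

**M-step.** The weighted negative objective is convex in each coordinate
block except $\beta$. Cyclic coordinate descent in the fixed order
$K \to \Sigma \to \bar d \to \alpha \to \beta$ uses closed-form weighted
least squares for $K$, a weighted residual second moment for $\Sigma$
(projected to the PSD cone by eigenvalue flooring at $10^{-8}$), a scalar
quadratic for $\alpha$ (clamped to $[0, 0.9]$), bounded 1-D solves on
$[0, 0.3]$ per droop factor, and a grid search for $\beta$ over $[0, 0.5]$
in steps of 0.005 (covers plausible pre-phasing at $\le 100$ cycles with
resolution below the estimate's sampling noise). Every update is accepted
only if it does not decrease the objective, so the trace is monotone; the
descent and the EM loop both stop when the relative objective change falls
below $\varepsilon = 0.003$, with safety caps of 50 coordinate cycles and
8 EM iterations per window.

**Scale updates.** After each window converges, the per-read scale is
refreshed as the positive root of the quadratic obtained by setting the
derivative of the window log-likelihood in $\lambda$ to zero:
$\sum_i \big[\,4\lambda^2 + b_i \lambda - c_i\,\big] = 0$ with
$b_i = (K X_i)^\top \Sigma^{-1} \bar Y_i / (D_i \lVert X_i \rVert^2)$ and
$c_i = \bar Y_i^\top \Sigma^{-1} \bar Y_i / (D_i^2 \lVert X_i \rVert^2)$,
where $\bar Y_i$ is the leakage-corrected observation. A positive root
always exists ($c_i > 0$), and the tests verify it coincides with a 1-D
numeric maximizer to $10^{-6}$. Window 1 bootstraps $\hat\lambda^k$ from
baseline calls; calling window $l$ of a new read uses the calls and
parameters of window $l-1$ the same way.

**Supervised variant.** When a reference is available (control lanes),
baseline calls are aligned to it; matches become point-mass per-position
priors and mismatches split their mass between the reference base
(`trust`, default 0.5) and the called base. The priors enter both decoding
and estimation through the product rule above. Reads the aligner rejects
fall back to uniform priors with a warning.

Within-window parameters are held constant ($K$, $\Sigma$, $\alpha$,
$\beta$ one value per window; droop per cycle): per-cycle values of all
parameters would be under-determined by 250 reads. When a window decode
needs pad cycles beyond its span, the span's parameters extend to them
with the current droop estimates for those cycles. At a window boundary the
leakage term uses the read's actual previous-cycle observation regardless
of which window it belongs to.

## The baseline caller

`bustard_call()` reproduces the classical matrix-inversion pipeline:
crosstalk from the first two cycles, inversion onto the observations,
per-cycle renormalization by the tile-average total signal (droop
correction), phasing correction by the pseudo-inverse of a strand-length
profile, and per-cycle argmax. The profile's rates are fitted by least
squares through the origin on the growth of lead/lag channel-leakage
fractions over the first 12 cycles; the classical procedure for this step
was never published in detail, so this fit is a documented approximation —
its qualitative behavior (perfect on clean or droop-only tiles, degrading
under phasing plus noise) is what the tests pin down. The baseline emits
no posteriors; its FASTQ qualities are written as a flat Q2.

## Quality scores and evaluation

Model-based calls take the per-position posterior of the called base as
their quality; FASTQ output maps posteriors through
$Q = \mathrm{round}(-10\log_{10}(\max(1-p, 10^{-4})))$ capped to
$[0, 40]$ — posteriors are routinely numerically 1, and an uncapped score
would be unbounded. Evaluation aligns calls to a reference by exhaustive
Hamming distance over all offsets and both strands (optionally circular,
for small phage-style references where wrap-around reads would otherwise
be penalized), retains reads with under 30% mismatches, and reports
per-cycle and overall error rates over retained reads only.
`discrimination_ability()` sorts bases by quality (stable sort; ties keep
their original order) and reports the largest prefix whose cumulative
error rate stays below a threshold; the threshold is a required user
parameter.

## Problem sizes in the shipped tests

The test suite validates decoding exactness on 200 random instances with
template length at most 8 (where exhaustive enumeration over all
sequences is feasible), parameter recovery on 250-read, 36-cycle tiles
across three seeds, decoder orderings on five seeded tiles of the same
size, and the scale quadratic on 50 random fixtures. These sizes are the
package's chosen trade-off between statistical resolution and a test run
of a few minutes on one core; the estimator itself has no dependence on
them.

## Known limitations

* One lookahead base only: at very high $p_{cf}$ or very long reads,
  two-ahead phasing mass becomes non-negligible and would require a
  64-state trellis (not implemented).
* $K$ and $\alpha$ are window-constant; real optics drift continuously.
* The Hamming evaluator is substitution-only; indel-producing effects are
  outside the signal model.
* The baseline's phasing-profile fit is an approximation of an unpublished
  procedure; comparisons against it are qualitative.
* Mate pairing is out of scope: each read of a pair is called
  independently.
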