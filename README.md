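# softcall

Model-based base calling for Illumina-style sequencing-by-synthesis
intensity data, with exact and approximate trellis decoders, windowed
online EM parameter estimation, a classical matrix-inversion baseline, a
generative tile simulator, and evaluation tools. It is aimed at people who
work on base-calling methods, signal models for short-read platforms, or
teaching material for HMM-style decoding — anyone who wants a complete,
testable implementation of this model class in R.

## The model

The intensity 4-vector observed for a cluster at cycle *i* is modeled as

    Y_i | Y_{i-1}  ~  N( λ·D_i·K·X_i + α·Y_{i-1},  (λ·D_i)²·||X_i||²·Σ )

where `K` is the 4×4 fluorophore crosstalk matrix, `α` an inter-cycle
leakage coefficient, `λ` a per-read scale, `D_i = Π_{j≤i}(1−d̄_j)` the
cumulative droop, `Σ` the multiplicative-noise covariance, and

    X_i = (1−β_i)·S_i + β_i·S_{i+1}

a two-term phasing approximation of the signal: because a cluster's
strands de-synchronize (no incorporation with probability `p_ii`, double
incorporation with probability `p_cf`), the cycle-*i* signal mixes template
positions, and at practical read lengths one lookahead base suffices.
Since `X_i` depends on the base *pair* `(S_i, S_{i+1})`, the sequence
posterior is computed by dynamic programming on a 16-state trellis whose
states are ordered base pairs:

* **forward–backward** — exact per-base posterior probabilities, used both
  for calling (argmax posterior; the posterior itself is the quality
  score) and as soft weights inside EM;
* **SOVA** (soft-output Viterbi) — the Viterbi path plus approximate
  posteriors from the best competing paths within 3-edge deviations;
  slightly less accurate, faster.

Parameters `Θ = {α, β, K, Σ, d̄_j}` drift along a run and are estimated
unsupervised, window by window (W = 6 cycles), by online EM: window 1 is
initialized from the first cycles and uses an importance-sampling E-step
over `λ`; later windows use posterior-weighted E-steps and a cyclic
coordinate-descent M-step (closed forms for `K`, `Σ`, `α`; grid search for
`β`). Per-read scales are positive roots of a window-wise quadratic.
A reference-supervised variant turns alignments of baseline calls into
per-position priors. The full generative model (with the *complete*
phasing profile, not the two-term approximation) backs `simulate_tile()`,
so the entire stack is testable against known truth. See the vignette
`vignettes/basecalling-model.Rmd` for the complete methods account.

## Worked example

Simulate a moderate-noise tile (150 reads × 24 cycles), train the model on
it, call bases with forward–backward, and score against the known truth:

```r
library(softcall)

cfg  <- sim_config(reads = 150, cycles = 24, seed = 42)
tile <- simulate_tile(cfg)
fit  <- train_basecaller(tile, train_reads = 150, seed = 42)
tidy(fit)
#> # A tibble: 4 × 7
#>   window start   end  alpha  beta droop_mean k_offdiag
#>    <int> <int> <int>  <dbl> <dbl>      <dbl>     <dbl>
#> 1      1     1     6 0.0568 0.05       0.0318     0.123
#> 2      2     7    12 0.0820 0.115      0.0314     0.117
#> 3      3    13    18 0.0917 0.155      0.0371     0.117
#> 4      4    19    24 0.0911 0.185      0.0357     0.116
```

The per-window estimates track the generative truth: droop was simulated
at 0.03 per cycle; the pre-phasing mixing weight `beta` grows along the
read as phasing accumulates (`p_cf` = 0.01); `alpha` and the crosstalk
off-diagonals match the simulated leakage and spectral overlap.

```r
calls <- call_tile(tile, fit, decoder = "fb")
calls
#> # A tibble: 3,600 × 5
#>   read    cycle base   qual phred
#>   <chr>   <int> <chr> <dbl> <int>
#> 1 1_1_1_1     1 A     1.000    40
#> 2 1_1_1_1     2 A     1.000    35
#> ...

error_rates(calls, truth = tile$truth)
#> <error_report> 150/150 reads retained, 3600 bases, overall error 0.0011
error_rates(bustard_call(tile), truth = tile$truth)
#> <error_report> 150/150 reads retained, 3600 bases, overall error 0.0042
```

The model-based caller makes 0.11% errors where the classical
crosstalk/phasing-inversion baseline makes 0.42% on the same tile, and its
posteriors are informative: sorting bases by quality, 3592 of 3600 are
callable before the cumulative error rate crosses 0.1%
(`discrimination_ability(calls$qual, correct, 0.001)`).

`write_fastq(calls, "tile.fastq")` emits Phred+33 FASTQ; `write_params()` /
`read_params()` serialize a fit. A thin command-line front end wraps the
same functions:

```sh
exec/softcall simulate --reads 250 --cycles 36 --seed 7 --out-prefix tile
exec/softcall call --int-file tile_int.txt --decoder fb --seed 7 --out tile.fastq
exec/softcall evaluate --fastq tile.fastq --truth tile_truth.fa --report report.tsv
```

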