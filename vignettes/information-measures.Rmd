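---
title: "Multivariate information measures for neural coding and transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate information measures for neural coding and transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popinfo)
```

popinfo computes information-theoretic quantities from trial-structured
neural data: how much information about a task variable is encoded by
single units or populations, how interactions between units shape that
information, how much of it is read out into behaviour, and how much of it
is transmitted — overall or about a specific task feature — between nodes
of a network. This vignette explains the estimators, the corrections, the
null models, the simulators, and the design choices behind them.

## The direct (plugin) method and its bias

Every estimate starts from discrete codes. Continuous signals are
discretized by `discretize()` with equispaced or equipopulated bins, user
edges, or integer pass-through with an optional cap (e.g. the three-letter
alphabet 0 / 1 / 2-or-more spikes). Conventions that matter for
reproducibility: equispaced bins are half-open with the last bin closed;
equipopulated edges are empirical quantiles of the full vector (never
per-class, which would leak label information) with ties sent to the lower
bin; codes are 0-based everywhere; multi-unit responses are joined by
mixed-radix flattening (`code_join()`). `auto_bin_count()` implements the
Freedman–Diaconis and Scott width rules.

Entropies and mutual informations are computed by plugging empirical cell
frequencies into the Shannon formulas, in bits, with `0 log 0 = 0` and no
pseudo-counts. This "plugin" estimator is consistent but biased upward at
finite trial counts: with `n` trials and an `R`-letter response alphabet the
leading bias of `I(S;R)` is of order `(R - 1)(S - 1) / (2 n ln 2)`. For a
binary stimulus and an 8-bin response at `n = 32` this is ≈ 0.16 bits —
often as large as the signal, which is why every applied pipeline in the
package runs through `corrected_mi()`.

## Limited-sampling bias corrections

Four corrections are provided, selected by `correction_spec()`:

* **shuffle_sub** — subtract the mean plugin MI over surrogates in which the
  pairing of the two variables is permuted away. Default for all
  figure-style pipelines (100 surrogates unless stated otherwise).
* **bootstrap_sub** — as above with resampling-with-replacement surrogates.
* **panzeri_treves** — the analytic first-order term, computed from naive
  counts of occupied response bins. On sparse tables the naive occupancy
  undercounts and part of the bias survives; this is a documented
  limitation of the occupied-bin variant, and the Bayesian occupancy
  refinement is deliberately out of scope.
* **quadratic_extrapolation** — plugin MI on the full data, on halves and on
  quarters (disjoint, stratified by the first variable to preserve class
  balance), solved exactly through `I_m = I_inf + a/m + b/m^2`. The half
  and quarter values are averaged over up to 20 repeated random splits;
  a single split's subsample variance otherwise swamps the bias removal at
  small `n`.

Corrected values may be negative; they are returned as-is. The package
validates the corrections on a binary-input channel whose response is a
Gaussian discretized into 8 fixed bins, so the true MI is available in
closed form from normal CDF differences and the bias dominates the sampling
noise at `n = 32..128` — the regime these corrections exist for. In the
opposite regime (2 × 2 tables, bias comparable to noise) no subtractive
correction reduces the mean absolute error, which is worth knowing before
reaching for one.

## Shuffling null models and permutation tests

`hierarchical_shuffle()` permutes one axis (trials, time bins, or units)
independently within strata defined by the class labels.
`shuffle_within_class()` is the most used special case: each unit's trials
are permuted within each stimulus class, preserving every class-conditional
marginal exactly while destroying the trial-by-trial co-variability between
units (the noise correlations). `permutation_test()` wraps any statistic
with the add-one p-value `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, one-sided
by default because information statistics are non-negative excess measures;
ties count toward the numerator, so `p` can never be zero.

## Decompositions: breakdown, RSI, PID, intersection information

`info_breakdown()` splits pairwise stimulus information exactly into
`I_lin` (summed single-unit information), `I_sig_sim` (signal similarity),
`I_cor_ind` (stimulus-independent correlations) and `I_cor_dep`
(stimulus-dependent correlations), built from the independent-conditional
reference distribution `P_ind(r|s) = Π_i P(r_i|s)`. The four terms sum to
the joint information identically, and `I_cor_dep` is an average
Kullback–Leibler divergence between the true and correlation-blind
posteriors, hence non-negative: it bounds the information lost by decoders
trained without considering correlations. The redundancy–synergy index is
`RSI = I_joint − I_lin`; positive means net synergy.

`pid()` decomposes the information 2 or 3 sources carry about a target on
the Williams–Beer redundancy lattice (4 or 18 nodes), by Möbius inversion
of a redundancy measure. Two measures ship: the specific-information
minimum `Imin` (default) and minimal-MI (`mmi`); both are exact,
dependency-free and desk-verifiable, and any other measure can be supplied
as a function, which is how an optimization-based redundancy would plug in.
For two sources the atoms satisfy the consistency equations
`UI_i + SI = I(S; X_i)` and `SI + UI_1 + UI_2 + CI = I(S; X_1X_2)` to
machine precision.

`intersection_information()` — the part of the stimulus information in
neural activity that is also used to inform the choice — is the redundancy
atom that response and choice share about the stimulus. The literature
leaves the orientation of that PID open; this package takes the minimum
over the two orientations (target = stimulus and target = choice), which
enforces `II ≤ I(S;R)`, `II ≤ I(S;C)` and `II ≤ I(R;C)` simultaneously.

## Transfer entropy and feature-specific transfer

`transfer_entropy()` computes `TE(X→Y; d, t) = I(Y_t ; X_{t−d} | Y_{t−d})`
across trials, per evaluation time; self-predictable dynamics drop out
through the conditioning. Pasts are scalar by default (`window = 1`);
longer embeddings are mixed-radix flattened. `conditional_te()` joins a
third node's past to the conditioning set.

`fit_transfer()` isolates the part of the transfer that is about a named
trial feature `S`. It is the minimum of two shared-unique lattice atoms:
in the decomposition of `S` by sources `{X_{t−d}, Y_t, Y_{t−d}}`, the atom
`PI({X_{t−d}}{Y_t})` — information about `S` shared by the sender's past
and the receiver's present, unique w.r.t. the receiver's past — and the
mirrored atom from the decomposition of `Y_t` by `{X_{t−d}, S, Y_{t−d}}`.
On the Williams–Beer lattice each atom equals a difference of two
redundancies, because the only node below `{A}{B}` that adds the
conditioning source is `{A}{B}{C}`. With `Imin` all lattice atoms are
non-negative, which yields the defining bounds
`0 ≤ FIT ≤ min(TE, I(S;Y_t), I(S;X_{t−d}))` by construction.
`conditional_fit()` joins a third node's past to the receiver-past source,
discounting feature information relayed through that node.

### Significance of transmission, and why the null matters

`transfer_sweep()` evaluates a measure on a (delay × time) grid and attaches
permutation significance. Two null schemes are available:

* **sender** (default): whole sender trials are permuted, within strata of
  the trial classes when `null_condition` is given. Permuting within
  classes retains all class-driven dependence — two nodes that both encode
  the stimulus but exchange nothing remain exactly as dependent under the
  null as in the data — so only *trial-specific* transmission is declared
  significant.
* **feature**: the feature labels are permuted across trials (FIT only).
  This tests whether any feature-related structure exists at all, but it
  cannot distinguish transmission from coincidental encoding at both ends:
  a receiver that gets the same feature from outside the network tests
  significant.

The edge-level statistic is the **centered max** over the grid: the
per-cell null mean is subtracted from both the observed grid and every
surrogate grid before taking maxima, so class-driven structure common to
observed and null cancels, and the max controls for the multiplicity of the
grid. The per-delay curve of these corrected peaks is also what locates the
communication delay.

## Decoder-based population information

The direct method cannot sample joint response probabilities beyond two or
three units. `decoder_info()` therefore trains a decoder (linear SVM, RBF
SVM, or GLM — binomial for two classes, multinomial otherwise) with
stratified k-fold cross-validation and computes bias-corrected MI between
true and decoded labels on the out-of-fold confusion table. This is a lower
bound on the population information that scales with population size; the
confusion-matrix route (rather than posterior probabilities) is the
package's default because it is what the validation scenarios specify.
Defaults of 2 folds (scaling analyses) and shuffle subtraction mirror those
scenarios; SVM hyperparameters are the e1071 defaults with feature scaling
off (binary spike counts can have zero-variance columns within a fold), and
they are recorded in the result. For binary problems the linear SVM's
discriminant vector is returned, and `axis_angle()` gives the absolute
angle between two such boundaries (e.g. stimulus vs choice axes) in
degrees. `reduce_dims()` offers PCA and a multiplicative-update NMF for
unsupervised compression; `scaling_curve()` maps information against
population size over random subpopulations (all subpopulations when few
exist), fits a quadratic in `log N`, and reports where the fit crosses a
reference level such as the behavioural information.

## The two simulators, and what they do and do not emulate

**Correlated populations** (`simulate_population()`): binary responses from
a dichotomized Gaussian — a latent equicorrelated Gaussian per stimulus,
thresholded so each unit attains its firing probability exactly while unit
pairs attain a requested count correlation (the latent correlation is
solved by 1-d quadrature of the bivariate normal rectangle probability, and
infeasible requests fail with the feasible bound). Two ready scenarios:

* `corr_coded` — identical marginals across stimuli, correlation 0.4 under
  stimulus 1 and 0 under stimulus 2 (N = 20, 500 trials per stimulus by
  default): all information lives in stimulus-dependent correlations, so
  single-unit information is zero, the breakdown loads on `I_cor_dep`, RSI
  is positive, only a non-linear decoder reads the population, and
  within-class shuffling destroys everything.
* `rate_coded_limited` — every unit fires more to stimulus 2 (0.35 vs
  0.65) with positive, weakly stimulus-modulated correlations (0.30/0.35):
  signal similarity makes pairs redundant (RSI < 0) and shuffling the
  correlations away *increases* decoder information.

The per-stimulus rates, correlations and trial counts are stated defaults
of this package, chosen once as typical cortical-recording magnitudes —
the qualitative contracts above, not the exact numbers, are the simulator's
specification. Binary (0/1) responses, equicorrelation, and Gaussian
latents are simplifications: real spike counts have larger alphabets,
heterogeneous tuning and structured correlations, so passing these tests
demonstrates correctness of the measures, not realism of the data.

**Four-node network** (`simulate_network()`): 60 ms of four continuous node
signals at 1 ms resolution, 1000 trials, two independent binary features
S1, S2 ∈ {−1, +1}. S1 is injected into X1 during 3–12 ms and into X4
during 15–24 ms; S2 into X2 during 3–12 ms; linear couplings with a 5 ms
delay implement X1→X2, X1→X3, X2→X1 and X3→X4. Injection gain, coupling
gain and noise SD all default to 1 (signal-to-noise 2:1 on a binarized
channel), values calibrated once so every ground-truth edge is significant
at p < 0.01 with 100 permutations in at least 9 of 10 repeats. The X3→X4
edge carries only X3's private signal (SD 1.5), which is active in its own
late window (30–50 ms), disjoint from X4's S1 window: the statement "the
X3→X4 exchange is not about S1 or S2" is thereby true *of the generated
data*, not merely an artifact threshold — with temporally overlapping
private exchange and feature arrival, any non-negative decomposition would
attribute some feature content to that edge. Analyses binarize each
(node, time) sample at its median (equipopulated, 2 bins).

## Numerical choices and degenerate inputs

All logarithms are base 2; zero cells are skipped rather than smoothed.
Breakdown sums are arranged so additivity holds identically (the four terms
are computed from shared arrays, and the identity is tested to 1e-10 on a
thousand random tables). Equipopulated binning collapses duplicate quantile
edges and flags the reduced alphabet. Classes with a single trial are left
unpermuted by the shufflers and flagged. A constant feature yields FIT = 0
with a warning, a constant choice yields II = 0 with a warning. Every
stochastic step takes an explicit integer seed and restores the caller's
RNG state, so identical seeds give bit-identical results and a seeded run
never perturbs the session's random stream.

## Problem sizes used by the validation suite

The shipped validation uses: exact identities on ~2,000 random tables;
bias-correction studies of 300 replicates at n = 32/64/128; population
scenarios with N = 20 units and 300 trials per stimulus; and 10 network
repeats of 1000 trials with 100-permutation edge tests on the full
(delay 1–10 × time) grid. These sizes were chosen so the full suite
documents every claim at conventional significance while remaining
comfortable to run on a laptop; all of them are parameters, and larger
studies only sharpen the same conclusions.

## Known limitations

* The direct method, PID and FIT are for small source sets (≤ 3); larger
  populations must go through the decoder pipeline.
* The occupied-bin Panzeri–Treves variant under-corrects sparse tables.
* `Imin` redundancy is known to over-count shared information in some
  systems; `mmi` and the plug-in interface exist for sensitivity analyses.
* FIT cannot, from data alone, distinguish transmitted feature information
  from feature information that arrives at both nodes from outside within
  the same lag window; the class-stratified sender null makes the test
  specific to trial-level transmission, and `conditional_fit()` discounts
  identified third-party routes, but unmodelled common input remains the
  caveat it always is in directed functional connectivity.
* Continuous-valued (nearest-neighbour / kernel / Gaussian-copula)
  estimators are not implemented; continuous data are discretized.
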