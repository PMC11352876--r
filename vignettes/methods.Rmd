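---
title: "Methods: augmentation, fuzzy features and swarm-tuned LSTM for EEG seizure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmentation, fuzzy features and swarm-tuned LSTM for EEG seizure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seizure detection from single-channel EEG is a binary sequence-classification
task: given a fixed-rate amplitude trace of a few tens of seconds, decide
whether it contains ictal (seizure) activity. The practically hard part is
data scarcity — labeled seizure segments are few — which motivates
label-preserving *random data augmentation* (RDA) of the training set, and
hyperparameter tuning of the classifier by population metaheuristics rather
than manual search. `seizr` implements the full chain and, because the
canonical public recordings cannot ship with a package, a synthetic generator
that reproduces their geometry so every stage is testable offline.

## The data model

An `eeg_record` is a finite amplitude sequence (microvolts) at a fixed
sampling rate with a class label. The reference geometry is one segment =
4097 samples at 173.61 Hz (about 23.6 s), one hundred segments per class,
with the positive class "seizure" and the negative class "non_seizure".

### What the synthetic generator emulates — and what it does not

Non-seizure segments are 1/f (pink) background noise plus a 10 Hz alpha-band
rhythm. Seizure segments share the background and add (i) biphasic
spike–wave bursts at `spike_rate` per second (default 3/s, the classic
spike–wave rhythm; sharp positive spike, slower negative wave) and (ii) a
20–30 Hz band-limited Gaussian component scaled by `seizure_beta_gain`
(default 4) — high-beta activity in this band is the conventional
physiological signature of anxiety and hyperarousal. Every record is further
scaled by a per-record amplitude factor drawn uniformly from ±40%
(`amp_jitter = 0.4`), because real EEG segments vary substantially in overall
amplitude between recordings and because amplitude variability is exactly
what the amplitude branch of RDA claims to model; without it, a synthetic
class is a single amplitude archetype and augmentation can only hurt.

The generator does **not** emulate: non-stationarity within a segment
(seizure onset/offset), electrode artifacts, inter-patient variability,
line noise, or realistic spectra beyond the 1/f + narrowband components. A
green end-to-end test therefore establishes that the pipeline's machinery is
correct and that its stages compose — not that the classifier would reach
comparable accuracy on clinical recordings.

## Preprocessing

**Band-pass.** Order-4 Butterworth band-pass, default passband 0.5–40 Hz
(covering delta through beta, including the 20–30 Hz band), applied
forward–backward (zero phase, squared magnitude response) with odd-reflection
end padding. The design is analog-prototype → lowpass-to-bandpass →
bilinear transform with prewarping, giving the −3 dB points exactly at the
band edges; `filter_response()` exposes the analytic magnitude response used
by the tests as an oracle. The published description mentions 1000 Hz and
100 Hz sampling in places; these conflict with the data's 173.61 Hz and are
treated as reporting artifacts — all filtering runs at the record's native
rate.

**Median filter.** A running median (default window 5 samples — small
enough to leave spike morphology intact) with symmetric, edge-including
padding; the window must be odd. The source text ambiguously says the filter
uses "the sequence's mean value"; a running median is the only reading
consistent with calling it a median filter, and is what is implemented.

**RADWT.** The rational-dilation wavelet transform is built as an iterated
two-channel filter bank in the DFT domain. At each scale the spectrum is
split by a power-complementary pair $|H|^2 + |G|^2 = 1$ (raised-cosine-sqrt
transition of total width $0.1\,f_c$ centered on the cutoff
$f_c = p/q$ of the current Nyquist); the lowpass branch keeps only its
possibly nonzero DFT bins, so its length shrinks by roughly $p/q$ per scale
— a rational dilation of $q/p$ (default $3/2$). Because only exactly-zero
bins are discarded, Parseval's theorem makes the construction a tight frame:
subband energies sum to the signal energy to machine precision and inversion
is exact (the tests require ≤ 1e-8 max-abs; observed ~1e-13). Detail bands
are kept at full rate (the redundancy parameter `s` is fixed at 1; other
values are rejected rather than silently approximated). If a record is too
short for the requested depth, the error names the maximum feasible level
count. The pipeline reconstructs from *all* bands by default — the source
work never states which bands, if any, are discarded — so the stage is an
analysis/synthesis identity that exercises the transform without changing
the signal.

## Random data augmentation

Three label-preserving transforms plus a combination, drawn uniformly per
variant with a seeded RNG:

* **amplitude**: $x \mapsto s\,x$, $s \sim U(0.5, 1)$ by default
  (reduction-only, following the stated emphasis on reduced seizure
  amplitudes; the range is configurable upward),
* **shift**: circular rotation by up to 10% of the length — circularity
  keeps the sample multiset, hence all amplitude statistics, unchanged,
* **width**: band-limited (FFT) resampling by $w \sim U(0.9, 1.1)$, then
  center-cropping ($w > 1$) or symmetric extension ($w < 1$) back to the
  original length, so every frequency scales by $1/w$ without aliasing.

Each variant records provenance (source id, transform, drawn parameters).
The augmentation factor and parameter ranges are not stated in the source
work; the defaults above are declared assumptions, and the scarcity
experiment (below) sets the amplitude range symmetric, $U(0.6, 1.4)$, to
match the generator's own per-record intensity spread — augmentation is a
model of the true variability, and a reduction-only range in a symmetric
world systematically shifts the training distribution.

## Features and fuzzy selection

Records are sliced into fixed windows (default 512 samples, no overlap;
8 windows per 4097-sample segment) and each window summarized by six
statistics: mean, variance (the first Hjorth descriptor, "activity"),
standard deviation, skewness $m_3/m_2^{3/2}$, kurtosis $m_4/m_2^2$
(population moments, non-excess; zero-variance windows return 0 by
convention) and Shannon entropy in bits over a 16-bin histogram spanning the
window's own min–max (amplitude-invariant by construction; empty bins
contribute nothing; a constant window has entropy 0).

Fuzzy C-means follows the canonical alternating optimization: centers are
$u^m$-weighted means, memberships are inverse squared-distance ratios with
exponent $2/(m-1)$, minimizing $J_m=\sum_{i,j} u_{ij}^m\|x_i-c_j\|^2$.
Defaults $c = 2$ (the seizure/non-seizure structure), $m = 2$, tolerance
1e-5 on the objective decrease, at most 100 iterations, seeded random
row-stochastic initialization. A point coinciding with a center receives
full membership there; $\varepsilon = 10^{-12}$ guards all divisions. The
objective is non-increasing by construction and the suite checks the final
memberships against an independently coded brute-force implementation.

"Selecting higher-membership-degree features" is ambiguous between columns
and samples; it is resolved as: rank columns by a separation score (distance
between cluster centers along the column divided by the pooled
membership-weighted within-cluster spread), keep the top $k$ (default 4) in
their original order, and append each sample's $c$ membership degrees as
extra columns — the selection both *uses* membership and *yields* a feature
matrix, and the memberships themselves carry the cluster geometry to the
classifier. For held-out data the memberships are computed against the
fitted centers.

In the pipeline, standardization statistics and the FCM fit come from the
*original* training records only, never from augmented variants: augmented
copies are amplitude-shifted by design, and letting them move the feature
center/scale would create a covariate shift between training and the
unaugmented test distribution (this was observed, and fixed, during
development).

## Optimizers

Both metaheuristics minimize; fitness is an error.

**PSO.** Velocities update as
$v \leftarrow \lambda v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$,
positions as $x \leftarrow x + v$, with $c_1 = c_2 = 2$, fresh uniform
$r_1, r_2$ per particle per dimension (injectable in tests), swarm size 9
and 100 iterations as reference settings. Velocities are clamped to 20% of
each dimension's range and positions clipped to bounds — without clamping,
$c_1 + c_2 = 4$ demonstrably diverges. The inertia $\lambda$ starts at 0.9;
`pso_optimize()` decays it linearly to 0.4 across the run. A fixed
$\lambda = 0.9$ is documented in the source material, but with $c_1=c_2=2$
it leaves the swarm oscillating (only 16/20 seeded 2-D sphere runs reached
1e-3); the linear decay is the canonical remedy and restores reliable
convergence (20/20). A standalone `pso_step()` keeps its state's fixed
$\lambda$, so the printed one-step update remains exactly testable.

**Parrot optimizer.** Population initialized uniformly in bounds; each agent
draws one of four behaviors per iteration, uniformly at random (the printed
model gives the equations but no selection rule; uniform selection matches
the original method):

* foraging: $(Y - Y_{best})\cdot levy(d) + r\,(1 - t/T)^{2t/T}\,\bar{Y}$,
* staying: $Y + Y_{best}\cdot levy(d) + r\,\mathbf{1}$,
* communicating: $0.2\,r\,(1 - t/T)(Y - \bar{Y})$ if $P \le 0.5$, else
  $0.2\,r\,e^{-t/(rT)}$ — implemented *as printed*, i.e. the new position
  replaces rather than increments $Y$,
* fear: $Y + r\cos(\tfrac{\pi}{2}\tfrac{t}{T})(Y_{best}-Y) -
  \cos(r\pi)\,(t/T)^{2/T}(Y - Y_{best})$, with the exponent $2/T$ kept
  exactly as printed even though it tends to 1 for large $T$.

Every occurrence of $r$ is a fresh uniform draw per agent per iteration;
$P$ is its own draw; `levy(d)` is a Mantegna Lévy flight with
$\beta = 1.5$ (the source writes only "levy(dim)"). Candidates are clipped
to bounds and accepted greedily — only if the objective improves. Greedy
acceptance is what makes the replace-style communicating equation safe: it
contracts positions toward small magnitudes, which would collapse the
population if always accepted, but under greedy acceptance it acts as an
increasingly fine local search around the origin-scale region late in the
run. Reference benchmark settings: 30 agents, 1000 iterations, dimension
30, bounds ±100.

**Hyperparameter coding.** Tuning happens on the unit cube with three
dimensions: learning rate (log-uniform on $[10^{-5}, 10^{-2}]$; midpoint
$10^{-3.5}$), hidden units (rounded onto 16…128), dropout (affine onto
$[0.1, 0.7]$). Coordinates are clipped before decoding, so decoding is
idempotent after a round trip.

## The LSTM classifier

A single recurrent layer with the standard gated update — gates
$\sigma(\cdot)$, candidate $\tanh(\cdot)$,
$c' = f \odot c + i \odot g$, $h' = o \odot \tanh(c')$ — over the sequence
of per-window feature vectors, followed by dropout on the final hidden state
and a two-class softmax readout. The published configuration table lists a
"regression layer" output, which conflicts with a binary task evaluated by
confusion matrices; a softmax classification readout is implemented. The
0.5 tie breaks to non-seizure (conservative in a screening framing; this
choice affects confusion matrices and is therefore fixed and stated).

Training is minibatch cross-entropy with full backpropagation through time,
global gradient-norm clipping at `gradient_threshold` (reference value 0.01,
read as a global-norm clip; under Adam's per-coordinate normalization a
uniform clip leaves the update direction essentially unchanged, so the small
reference value remains trainable), and adaptive-moment updates by default
(plain SGD behind a flag — the source says only "backpropagation").
Reference values: 100 hidden units, learning rate $10^{-4}$, dropout 0.5.
Epochs (30) and batch size (16) are not stated anywhere and are desk-scale
defaults. Initialization is seeded uniform ±0.08 with zero biases, which
puts the first-epoch loss of a balanced task near $\ln 2$. Everything —
shuffling, dropout masks, initialization — derives from one seed, and
training is bitwise reproducible.

`cv_fitness()` decodes a position, runs stratified $k$-fold cross-validation
and returns $1 - $ mean validation accuracy: a deterministic function of
(position, seed), as coherent optimization requires.

## Pipeline and the BDA/ARDA comparison

Stages: load/generate → band-pass → median → RADWT analysis/synthesis →
stratified 70/30 holdout → (ARDA arm only) augment the *training* side →
features (+ FCM selection for `fcm_ps_lstm`) → hyperparameter search over
CV fitness on the training side (10-fold for the PSO variants, 5-fold for
`po_lstm`) → final training → metrics on the held-out side. The holdout
nests the cross-validation: CV tunes inside the 70%, the 30% is touched once.

Splitting precedes augmentation so variants can never leak across the
split; the held-out set contains only unaugmented records, which also makes
the BDA and ARDA arms of `compare_bda_arda()` share an identical test set.
The leak-prone augment-then-split ordering is available behind
`paper_ordering = TRUE` (with a warning) for comparison. A hard leakage
check — no source root on both sides — runs on every default-ordering run.

## Numerical choices, degenerate inputs, tie-breaks

* All 0/0 metric ratios are 0 by convention; MCC/kappa are reported ×100 to
  match the conventional 0–100 presentation (raw scale via
  `percent = FALSE`); rounding to 2 d.p. happens only at rendering.
* FCM: coincident points get full membership; $c = 1$ short-circuits to the
  closed form (center = column means, memberships 1).
* RADWT: levels infeasible for a record length produce an error naming the
  feasible maximum; tampered subband lengths produce a consistency error.
* Optimizers: non-finite objective values become $+\infty$ with a warning
  (PSO) or candidate rejection (PO); histories are best-so-far and hence
  non-increasing by construction; total evaluations are exactly
  population × (iterations + 1).
* Width warping guards odd/even lengths in its spectrum surgery (a shared
  Nyquist bin is split evenly); the minimum resampled length is 2.
* All randomness flows through an internal `with_rng()` that saves and
  restores the caller's RNG state: package calls never perturb a user's
  stream, and derived seeds stay below $2^{31}$.

## Known limitations

* The synthetic world is stationary within a segment and linearly
  separable enough that held-out accuracies saturate near 100%; results on
  it bound nothing about clinical data.
* The fuzzy "if–then" inference narrative in the source has no concrete
  rule base and is not implementable as stated; only the FCM clustering and
  membership-based selection are realized.
* Only `s = 1` RADWT redundancy is supported.
* No EDF/BDF input, no multi-channel montages, no GAN-style augmentation,
  no ROC/AUC (not part of the reported evaluation).
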