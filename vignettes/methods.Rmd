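---
title: "Methods: EEG staging from phase-locking networks, spatial filters and recurrence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG staging from phase-locking networks, spatial filters and recurrence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adeeg` analyses multichannel EEG of Alzheimer's disease patients whose
recordings clinicians have staged into three states — calm, transitional and
morbidity — distinguished chiefly by the magnitude and irregularity of
amplitude fluctuation. Three decision branches are computed per recording and
fused at the probability level:

1. **PE branch** — a phase-locking-value (PLV) functional connectivity
   network plus common-spatial-pattern (CSP) features, classified by
   multinomial logistic regression;
2. **RE branch** — an unthresholded recurrence-plot image classified by a
   small residual convolutional network;
3. **clinical branch** — a multinomial model over covariates that survive a
   p < 0.05 screen.

This vignette records the model assumptions, the numerical choices and the
places where the design was genuinely open, so a maintainer can see why the
package behaves as it does.

## Phase synchronisation and the PLV

For two channels with instantaneous phases $\varphi_x(t)$, $\varphi_y(t)$,

$$\mathrm{PLV} = \frac{1}{N}\left|\sum_{j=0}^{N-1}
  e^{\,i\,(\varphi_x(j\Delta t)-\varphi_y(j\Delta t))}\right|,$$

the modulus of the time-averaged unit phasor of the phase difference. The
phase-extraction method is not dictated by the quantity itself; we use the
standard construction: a 4th-order Butterworth band-pass (default 8–30 Hz)
applied forward and backward so it is zero-phase, followed by the analytic
signal (FFT method) whose angle is the instantaneous phase. $\Delta t$ is the
sample period and the sum runs over the full window; a `trim_edges` flag
(default off) drops the first and last 5 % of samples when filter transients
matter, and `plv_sliding()` offers an exploratory windowed variant (phases
extracted once, PLV per window) while the full-window value remains the
primary quantity. Since $N$ is positive the placement of $1/N$ inside or outside the
modulus is immaterial; we compute the modulus of the mean.

Calibration anchors used by the tests: identical or constant-offset phase
series give PLV = 1 to machine precision, and independent uniform phases give
$E[\mathrm{PLV}] \approx \sqrt{\pi}/(2\sqrt{N})$ (the mean resultant length
of a 2-D random walk), about 0.028 at $N = 1000$.

## The brain network and its metrics

The PLV matrix is read as the weighted adjacency $c_{ij}$ of an undirected
graph on the channels with zero diagonal. For path-based metrics an edge's
traversal length is $1/c_{ij}$ — strong synchrony is a short functional
distance — with $c_{ij}=0$ meaning no edge. A hop-count mode is available
because the path-length prose speaks of "number of edges", but reciprocal
lengths are the default for weighted brain graphs. Disconnected pairs
contribute $1/L_{ij}=0$ to efficiencies and are excluded from the
characteristic-path-length mean.

* weighted clustering $C_i = \sum_{k\ne l} c_{ik}c_{il}c_{kl} \big/
  \sum_{k\ne l} c_{ik}c_{il}$ (indices exclude $i$; 0 when the denominator
  vanishes);
* characteristic path length $L$ = mean shortest-path length over ordered
  pairs. The printed normalisation that would multiply a *sum of
  reciprocals* by $N(N-1)$ duplicates the efficiency formula and contradicts
  its own prose, so the standard mean is implemented and the reciprocal form
  is covered by $G$;
* global efficiency $G$ = mean of $1/L_{ij}$; local efficiency $Le_i$ = $G$
  of the subgraph induced by $i$'s neighbours; 0 with fewer than two
  neighbours;
* betweenness $b_i = \sum_{m\ne i\ne n} \sigma_{mn}(i)/\sigma_{mn}$ over
  unordered pairs, where path counts treat lengths tied within a relative
  $10^{-9}$ as equal.

A second betweenness mode (`paper_fig2`) reports a *relative through-share*:
over the ordered pairs that route through node $i$, $i$'s fractional
through-count divided by the total through-counts of all intermediates on
those pairs. On a two-branch relay network (source and sink joined by two
parallel two-edge branches) each relay carries half of the two shortest
source–sink paths and its share is $ (0.5+0.5) / (0.5+0.5+1.0) = 1/2$. A
plain global share $b_i/\sum_k b_k$ was rejected: the endpoints of the
branches also relay traffic between the two mid-nodes, which drives the
value to 1/4 and cannot reproduce the worked arithmetic.

## Common spatial patterns

Per trial $X$ (channels × samples) the normalised covariance is
$R = XX^\top/\mathrm{tr}(XX^\top)$. With class averages $\bar R_1, \bar R_2$
and composite $R_c = \bar R_1 + \bar R_2 = U_c \Lambda_c U_c^\top$, the
whitening transform is $P = \Lambda_c^{-1/2} U_c^\top$. (A printed variant
$P = U_c^\top \Lambda_c$ cannot satisfy the constraint
$\Lambda_1 + \Lambda_2 = I$ that defines the method, so the standard form is
used; the package asserts $P R_c P^\top = I$ on every fit.) The whitened
class covariances share eigenvectors $B$, and $W = (B^\top P)^\top$ holds the
spatial filters, columns sorted by decreasing class-1 eigenvalue and
sign-fixed so each column's largest-magnitude entry is positive. A ridge
$\lambda I$, $\lambda = 10^{-6}\,\mathrm{tr}(R_c)/M$, guards rank deficiency
and can be disabled.

Feature extraction from $Z = W^\top X$ keeps the first and last $m$ rows.
"The maximum values of the $2m$ rows" is ambiguous, so both readings exist:
`paper_max` (literal row maxima of $|Z|$, amplitude-carrying) and the
standard `log_variance` (log of normalised row variances, scale-invariant),
the default. CSP is strictly two-class, so the three-state problem uses
one-vs-rest banks whose features are concatenated.

## Recurrence representations

A series is delay-embedded ($m$, $\tau$), pairwise state distances
$r_{ij} = \lVert X(i)-X(j)\rVert$ are computed (Euclidean default; Chebyshev
and Manhattan available), and either the classic thresholded plot
$R_{ij} = \varphi(\varepsilon - r_{ij})$ or the unthresholded variant
$ER_{ij} = |\varepsilon - r_{ij}|$ is formed. The unthresholded transform
keeps the continuous dynamical structure a binary plot discards. The
defaults are the paper-faithful ones: $m = 1$, $\tau = 1$ so 1000 samples
give a 1000 × 1000 matrix, and $\varepsilon = 0$, the maximally
information-preserving choice under which $ER = r$ exactly; $\varepsilon$ may
also be set absolutely or as a quantile of the off-diagonal distances.
Embedded mode defaults to $m = 3$, $\tau = 4$ when explicitly requested.

For the CNN the matrix is block-mean downsampled to a configurable side
(64 by default; bins are near-equal when the input side is not a multiple)
and scaled to [0, 1] per image (min–max; a constant matrix maps to zeros).
Per-image scaling discards absolute amplitude — deliberately, so the CNN must
learn the *texture* of the dynamics rather than a trivial brightness
threshold; a `global` fixed-scale mode exists for cross-image comparability.

## The residual image classifier

The network follows the printed layer table: a 7 × 7, 64-channel stride-2
convolution, then eight residual blocks of paired 3 × 3 convolutions with
widths 64, 64, 128, 128, 256, 256, 512, 128, max-pooling after the first two
blocks, and a head of global average pooling into a 3-way softmax. "D = 2"
entries are read as stride/pool downsampling, not dilation: with three D = 2
entries and two poolings a dilation reading would never reduce resolution.
Each "× 2" entry is one residual block; 1 × 1 projection shortcuts bridge
channel changes. The final drop from 512 to 128 channels is unusual but is
implemented as printed, with a `monotone` flag for the conventional profile.

Training details the source leaves unspecified were fixed as: batch
normalisation before every ReLU with the second BN of each block initialised
at $\gamma = 0$ (the network starts as an identity-like shallow net and the
residual branches fade in), He-initialised weights, Adam at $10^{-3}$, batch
16, 30 epochs with a ×0.1 step decay over the final third — the decay pins
the last epochs to the converged plateau so the reported final-epoch
validation accuracy is not an artefact of late-training oscillation.
Everything is seeded: weight initialisation, the stratified
train/validation split and the per-epoch shuffles, so reruns reproduce
training trajectories to within single-precision accumulation (losses agree
to ~1e-4). Inference uses running BN statistics and is bit-stable. The
implementation is single-precision C++ (im2col + BLAS sgemm) sized so a
full 30-epoch run on 112 training images at side 64 takes a few minutes on
one CPU core.

## Screening, probability models and fusion

Clinical covariates are screened across the three states: Kruskal–Wallis for
continuous features, chi-squared independence for binary ones (Fisher's
exact test when an expected cell count falls below 5). No multiple-testing
correction is applied by default, mirroring the bare p < 0.05 screening rule
(a `correction` argument accepts any `p.adjust` method). With three null
covariates at a bare per-feature α = 0.05, the probability of selecting
*exactly* the three truly informative features is capped near
$(1-\alpha)^3 \approx 0.86$ even at power 1 — a property of the screening
rule itself, worth remembering when interpreting exact-recovery rates.

The PE classifier is multinomial logistic regression (seeded,
L2-regularised, standardised inputs) over the concatenated CSP features and
network metric vector $[C_1..C_N, L, G, Le_1..Le_N, b_1..b_N]$. A literal
"feed the features into the PLV network" graph-classifier reading has no
support in the source text and was rejected. The clinical model is the same
family over screened features only; an empty screen yields the uniform
distribution with a warning. Fusion operates on decision probabilities:
arithmetic mean, fixed convex weights, or (default) a stacked multinomial
meta-classifier fitted on a fold held out from base-model training.
Evaluation is one-vs-rest per state — accuracy $(TP+TN)/(TP+FP+TN+FN)$,
macro average, and ROC/AUC via threshold sweep (the AUC equals the
concordance statistic; ties share thresholds).

## The synthetic study

No clinical recordings ship with the package, so a seeded generator defines
the study conditions end to end.

**Signals.** Each channel is an amplitude-modulated cosine plus white noise,
band-passed to 8–30 Hz at $f_s = 128$ Hz, 1000 samples per recording, four
channels labelled Fp1/Fp2/F3/F4 by default (62-channel generation is
supported). A channel's phase mixes its own random phase walk (step 0.15
rad/sample, carrier drawn within ±3 Hz of band centre) with a single shared
walk; the mixing weight is $\max_j \kappa_{ij}^{1/4}$, the quarter power
spreading recovered PLV visibly across $\kappa \in \{0, 0.3, 0.6, 0.9\}$
(≈ 0.09 / 0.16 / 0.24 / 0.65 over 50 seeds). $\kappa$ near 1 yields PLV
above 0.9; independent channels stay below 0.2 on average because their
carriers differ and their walks decorrelate.

**States.** Amplitude profiles give the three states gains 1 / 2 / 4 and
burst volatilities 0.10 / 0.45 / 0.80 (slow ~0.5 s envelope bursts), so
pooled variance orders the states strictly — a variance threshold alone
stages recordings at ≥ 90 % — while the burst *texture* survives per-image
min–max scaling and is what the CNN actually learns. A per-state spatial
gain pattern (uniform; Fp2-weighted; F3/F4-weighted with frontal reduction)
emulates the spatial redistribution of power with disease progression and
gives the scale-invariant CSP features class information. Each synthetic
subject contributes one recording per state, and all splits are
subject-level.

**Clinical table.** Age, diabetes and eye-movement score carry real effects
(Cohen's d = 1.0 per adjacent state for continuous features; risk
difference 0.3 per adjacent state for diabetes, i.e. prevalence
0.15/0.45/0.75); sex, hypertension and hyperlipidemia are label-independent.
The per-adjacent-state reading of the effect sizes was chosen because the
total-range reading leaves the binary test underpowered (~0.6) at n = 100,
while these defaults are comfortably detectable. One clinical row is
generated per recording, aligned by label.

**What the generator does not emulate:** ocular/muscle artifacts, volume
conduction, 1/f spectral shape beyond band-passing, non-stationary coupling,
or realistic channel covariance. Passing tests therefore demonstrate the
pipeline's correctness and its ability to recover known structure — not
clinical performance on real EEG.

## Problem sizes and determinism

The shipped experiments use desk-scale sizes chosen to keep a full run in
minutes on a single core: 150 recordings (50 subjects per state), 1000
samples each, recurrence images at side 64, 30 training epochs, CSP toy
problems with 500 trials per class, Monte-Carlo calibrations with 50–1000
replicates. Every stochastic step takes an explicit seed; `run_pipeline`
derives per-stage seeds from one master seed and records them in its report.
Known numerical edge cases are pinned by tests: negative-ε recurrence plots
zero the diagonal, constant images scale to zero, zero-power trials and
identically-zero channels raise errors rather than NaN, and fusion weights
that do not sum to one are renormalised with a warning.

## Limitations

The clinical branch and fusion are only as meaningful as the covariate
table; on real data the screened set varies with cohort size. The exact-set
screening ceiling noted above applies to any bare-α screen. The CNN is
sized for 64–128-pixel images on a CPU; the 1000-pixel paper-faithful input
is supported but slow to train. ROC curves for the comparator algorithms in
the source literature are out of scope, as is validation on the authors'
cohort, which is not publicly deposited.
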