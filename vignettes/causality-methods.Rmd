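---
title: "Causality detection and root-cause analysis with causalrca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causality detection and root-cause analysis with causalrca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalrca)
```

## The problem

When a fault or an abnormal discharge originates at one node of a coupled
system — a sticking valve in a chemical plant, a seizure onset zone (SOZ)
in an epileptic brain — it propagates along the system's couplings until
the disturbance is plant-wide or brain-wide. Root-cause analysis asks the
inverse question: given only multichannel recordings, which node drove the
others? `causalrca` answers it by estimating *effective connectivity*
(directed, causal influence, as opposed to symmetric correlation) with
several complementary method families, testing each detected edge for
significance, and ranking nodes by their **causal information outflow**

$$\mathrm{outflow}(X_i) \;=\; \sum_{j \ne i} \mathrm{Causality}(X_i \to X_j),$$

the driving force a node exerts on the rest of the network.

No single causality measure dominates: linear multivariate measures excel
on near-stationary process data, spectral measures on oscillatory
recordings, information-theoretic measures on nonlinear couplings, and
state-space cross mapping on deterministic dynamics. The package therefore
implements all of them behind one data model, so the same recording can be
pushed through every method and the results compared under one evaluation
framework.

## Data model and preprocessing

An `mv_series` holds an $n \times T$ channel-by-sample matrix, a sampling
rate `fs` (Hz), unique channel labels and optional region tags. Readers
exist for header-CSV matrices (the sampling rate is supplied by the caller,
since the format carries none) and EDF, the standard container for
intracranial EEG; a matching writer pair supports round-trip tests and
export of synthetic fixtures.

Band filtering is always zero-phase (forward–backward Butterworth): a
one-pass filter's frequency-dependent group delay would shift channels
relative to each other and masquerade as causal lag in every
delay-sensitive estimator downstream. `standardize()` enforces zero mean
and unit variance per channel so scale-sensitive measures (TE bins, CCM
distances, cross-correlation) compare fairly across channels with
different physical units. `sliding_windows()` tiles a recording into
half-open, 0-based windows of `round(width_s * fs)` samples — at 500 Hz a
5 s window is exactly 2500 samples — discarding a trailing partial window
so every segment has identical size.

## Method families

### Granger causality and its multivariate form

Each channel is regressed on the lagged past of all channels (an MVAR
model, least squares with an intercept; the intercept is harmless on
de-meaned data and protects against non-centered input). The causality
from $X_j$ to $X_i$ is
$F_{j\to i} = \ln\!\big(\mathrm{var}(e_i^{(j)})/\mathrm{var}(e_i)\big)$,
comparing the restricted model (channel $j$ excluded) with the full one.
The model order is chosen by BIC over `1..p_max`, ties broken toward the
smaller order (parsimony). Bivariate GC uses the classical F test on
residual sums of squares with $(p,\,T-2p-1)$ degrees of freedom; MVGC uses
the likelihood-ratio form $(T-p)\,F_{j\to i} \sim \chi^2(p)$, which
follows directly from the log variance ratio. Both default to a per-pair
$\alpha = 0.001$ with no multiple-testing correction (a Bonferroni option
exists but is off by default, matching the per-pair convention of the
reference analyses). The multivariate form is what rules out indirect
edges: on a simulated chain $X_1 \to X_2 \to X_3$ the restricted model for
$X_3$ without $X_1$ loses nothing once $X_2$ is present.

### Spectral measures: DTF, PDC and their extensions

From the fitted MVAR, $A(f) = -\sum_{l=0}^{p} A_l e^{-2\pi i f l / f_s}$
with $A_0 = -I$, and $H(f) = A(f)^{-1}$. The DTF
$\gamma_{ij}(f) = |H_{ij}(f)| / \sqrt{\sum_k |H_{ik}(f)|^2}$ is
row-normalized (inflow view, includes cascaded routes); the PDC
$\pi_{ij}(f) = |A_{ij}(f)| / \sqrt{\sum_k |A_{kj}(f)|^2}$ is
column-normalized (outflow view, direct links only). Both normalizations
are exact identities — the squared row of DTF and squared column of PDC
each sum to one at every frequency — and the test suite verifies them to
1e-10 on random stable models. The printed formulas admit an alternative
"squared sum" reading; only the root-of-summed-squares denominator makes
the unit identities hold, so that reading is used.

Two extensions serve band-level analysis. The full-frequency DTF pools the
row denominator over the whole analysis band, making magnitudes comparable
across frequencies instead of renormalized at each one. The
spectrum-weighted DTF/PDC multiply the base measure by the *source*
channel's parametric PSD $S_{jj}(f) = [H(f)\Sigma H(f)^*]_{jj}$,
normalized to sum to one over the band, so frequencies carrying more
energy count more. Source-side weighting was an open choice (target-side
is also defensible); the source side is what makes the weighting answer
"where does the energetic drive come from", which is the RCA question.
Band aggregation sums the per-frequency values over grid frequencies in
the band (inclusive ends). The default grid is 129 evenly spaced points
from 0 to the Nyquist frequency.

### Transfer entropy and direct transfer entropy

$T_{X\to Y} = H(Y_{t+h}\mid Y^-_t) - H(Y_{t+h}\mid X^-_t, Y^-_t)$, in bits
(base-2 logarithms throughout; the base is a reporting convention, not a
modeling choice). The default estimator discretizes each embedded
coordinate into 4 equiprobable rank bins and uses plug-in entropies:
robust at a few thousand samples, and invariant under strictly monotone
rescaling by construction. Defaults $h = l_1 = l_2 = \tau = 1$ keep the
embedded dimension low; the estimator refuses more than 12 embedded
dimensions and points to the Kraskov-style knn estimator provided for
continuous data. Small negative estimates are reported raw in diagnostics
but clamped to zero in matrices.

DTE conditions the same difference on the embedded pasts of other
channels. The conditioning set for a TE-significant edge $X \to Y$ is
every channel $Z$ that the TE graph itself marks as a common cause
($Z \to X$ and $Z \to Y$) or a mediator ($X \to Z$ and $Z \to Y$); the
edge survives only if the DTE given that set beats its own surrogate
threshold. This operationalizes "condition on the detected common causes
and mediators" with the information available at pruning time, without
assuming unobserved structure.

### Convergent cross mapping

CCM exploits that if $X$ drives $Y$, then $Y$'s delay embedding contains a
copy of $X$'s dynamics, so $X$ can be estimated from the manifold of $Y$:
nearest-neighbor weights $u_i = \exp(-d_i/d_1)$ over the $K$ closest
library points, skill $\rho$ = Pearson correlation between estimate and
truth. The causal effect $X \to Y$ is quantified by cross-mapping $X$ from
$M_Y$. Libraries are increasing prefixes of the recording, matching the
"increasing length of the time series" convergence protocol. A Theiler
exclusion window of $\dim\cdot\tau$ samples keeps temporally adjacent
points out of the neighbor set; on oscillatory data its absence produces
spuriously convergent skill from pure autocorrelation, which is exactly
the false-positive mode oscillating process data provokes. Convergence is
declared when the curve has flattened — least-squares drift over the last
half of the sweep at most `tol` (default 0.05) and
$|\rho(L_{max}) - \rho(L_{max}/2)| <$ `tol` — and significance requires
convergence with $|\rho| > 0.75$ *strictly*. The reference analyses judge
convergence visually; this quantitative rule is the package's own
operationalization, and negative convergent $\rho$ counts via the absolute
value while the sign is preserved in the output. Defaults (dim 18, delay
1, $K = 8$) follow the reference parameterization for real recordings;
for the logistic-map benchmark a dimension of 3 is the canonical choice.

### Lag and phase directionality

The cross-correlation function evaluates
$\rho_{XY}(\tau) = \mathrm{cor}(x_t, y_{t+\tau})$ over an integer lag
range; the best lag (maximal $|\rho|$, ties toward the smallest $|\tau|$)
gives the delay and its sign the direction, with $\hat\tau > 0$ meaning
$X$ leads. The phase slope index sums
$\mathrm{Im}\,C^*_{XY}(f)\,C_{XY}(f+\delta f)$ over band frequencies,
where $C_{XY}$ is the complex coherency estimated Welch-style
(Hann-tapered segments, 50% overlap, 1 s default segment length,
$\delta f$ = grid spacing). The sign convention is calibrated so a sender
feeding a delayed copy yields positive $\psi$ for the sender-to-receiver
orientation (with $S_{XY} = X(f)\overline{Y(f)}$, a transmission delay
$d$ contributes a phase increment $e^{+2\pi i\,\delta f\, d}$ per grid
step, hence a positive imaginary sum). The normalized variant divides by
the leave-one-segment-out jackknife standard deviation and needs at least
4 segments. Both CCF and PSI are bivariate and degrade under dominant
bidirectional coupling — one reason they underperform on cortical data.

## Surrogate significance

TE, DTE and the spectral measures have no convenient analytic null, so
thresholds come from Monte Carlo surrogates: each channel of a couple is
surrogated independently, the measure is evaluated on many such couples,
and the threshold is null mean + $k$·SD ($k = 3$ for time-domain
measures, 2 for DTF/PDC, following the reference settings; 3000 couples
is the reference count, and reduced counts are used for desk-scale runs).
The default surrogate is IAAFT, which preserves both the power spectrum
and the amplitude distribution — the appropriate null for oscillatory
data, where a spectrum-destroying shuffle would make any rhythmic channel
look causal. Phase randomization and plain shuffling are selectable. For
DTF/PDC the MVAR is refitted on every surrogate replicate, so the
threshold curves reflect the full estimation pipeline, not just the
measure. Thresholding is monotone in $k$ by construction.

## Root-cause tooling

`build_graph()` turns a significant-edge matrix into a directed graph;
`information_outflow()` computes the node statistic either
significance-masked (for graph reasoning) or raw (for heatmaps — a
continuous color scale is more informative than a binary mask, so both
modes are exposed). `dynamic_outflow()` repeats any method over sliding
windows, flagging failed windows rather than aborting; `rank_sources()`
assigns windows to epochs by midpoint (unbiased for symmetric windows) and
ranks nodes by median outflow in the ranking epoch (the epoch named
"ictal" when present). `propagation_path()` extracts the maximum-weight
spanning arborescence rooted at a chosen node (Chu–Liu/Edmonds; the
reference work presents propagation paths without an algorithm, and the
maximum-weight arborescence is the canonical weighted generalization),
reporting unreachable nodes separately. `evaluate_edges()` scores a
detected graph against ground truth with directed-edge precision and
recall.

## Synthetic study conditions

The generators define the package's test beds and are first-class, seeded,
deterministic code:

- `gen_var_network()`: linear VAR data with exactly the specified directed
  couplings; coefficients are rescaled deterministically (scaling lag-$l$
  matrices by $s^l$ scales all companion eigenvalues by $s$) to spectral
  radius 0.95 when needed, rather than rejection-sampled.
- `gen_oscillatory_network()`: the plant-wide oscillation case — the root
  node carries a clipped sinusoid (amplitude clipping of a limit cycle is
  the standard cartoon of valve stiction: a harmonic-rich near-square
  wave), defaults 8640 samples at 20 s intervals (48 h) with a period
  near 2 h, and each true edge applies lag plus first-order low-pass
  smoothing, so all channels share the common spectral peak.
- `gen_coupled_logistic()`: the canonical chaotic CCM benchmark,
  $x_{t+1} = x_t(r - r x_t - \beta_{yx} y_t)$ and symmetrically for $y$,
  with burn-in discarded.
- `gen_switching_network()`: the SOZ case — designated source nodes whose
  outgoing coefficients are multiplied per epoch (0.5 before, 1.6 during
  the "ictal" epoch, 0.8 after, chosen as weak/strong/relaxed coupling
  within stable range), driven by 1–30 Hz band-limited innovations at
  250 Hz. The three 20 s epochs at 250 Hz keep a desk-scale problem while
  leaving dozens of 5 s windows per epoch.

What these emulate — and what they do not: the generators produce the
*structural* signatures the methods key on (directed lagged couplings, a
shared oscillation, epoch-switching drive). They do not emulate
measurement noise mixtures, volume conduction, nonstationary drift within
epochs, artifacts, or the heavy-tailed amplitude statistics of real iEEG.
Passing tests therefore demonstrate method correctness and the expected
qualitative contrasts, not field performance on any particular real
recording.

## Numerical choices and degenerate inputs

Constant channels are rejected by name wherever variance or ranks are
needed. Rank-deficient MVAR designs (duplicated channels) raise an error
rather than silently pseudo-inverting. `var_to_spectral()` refuses
unstable models (companion spectral radius ≥ 1) and reports the frequency
if $A(f)$ is near-singular (condition number > 1e12). Exact-match CCM
neighbors ($d_1 = 0$) receive the full weight of the zero-distance set
instead of dividing by zero. A constant surrogate metric yields its own
value as threshold (SD = 0). TE estimates below zero are clamped only in
reported matrices. Window counts use `floor((T - w)/s) + 1` with half-open
index arithmetic, so segment counts are exact.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at deliberately desk-scale
sizes chosen to make the statistical contrasts decisive on one core: 100
random models for the normalization identities; 50 five-channel null
networks ($T = 2000$) for type-I control with 100 surrogate couples; 20
seeds for network recovery and chain pruning; $T = 10000$ for the
binary-copy transfer entropy; $T = 3000$ logistic maps for CCM; and ten
seeds of the 12-node switching network for the sliding-window ranking.
The reference surrogate count of 3000 couples remains the config default
for real analyses.

## Known limitations

Time-varying MVAR (Kalman-filter style) estimation is out of scope — the
sliding-window refit is the supported route to dynamics. TE surrogate
thresholds at 100 couples are noisier than at the reference 3000; the
mean + 3SD form absorbs most of that, but borderline edges can flip
between runs with different surrogate seeds. The binned TE estimator
saturates above ~12 embedded dimensions (use the knn estimator there).
CCM significance uses only the convergence-plus-threshold rule, not
surrogate ensembles. PSI and CCF are bivariate by construction and cannot
rule out common drivers; that is precisely the failure mode the
multivariate measures (MVGC, DTE, ffDTF, swPDC) exist to address.
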