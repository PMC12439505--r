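---
title: "Wavelet energy indices for PERG: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet energy indices for PERG: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pergdwt)
```

## The problem

Pattern electroretinograms quantify macular cone and retinal ganglion cell
function through three canonical components: N35 (negative, ~35 ms), P50
(positive, ~50 ms) and N95 (negative, ~95 ms). The conventional markers —
the |P50−N35| and |N95−P50| amplitude differences and the components'
implicit times — require the peaks to be identifiable, which is exactly
what disease erodes: in macular-predominant inherited retinal disease the
P50 deflection flattens until peak picking becomes guesswork. A
time-frequency energy index sidesteps this: it integrates signal power
over a fixed window, needs no landmark detection, and remains defined on a
flat trace.

## The transform

Each preprocessed trace has 256 samples spanning 150 ms at 1700 Hz (the
native 255-sample window is detrended by subtracting its mean — a
zero-order fit, deliberately leaving slopes intact — and the final sample
is repeated once to reach dyadic length). The multilevel DWT is computed
with *periodized* extension: the trace is treated as circular, which is
both physically sensible (PERG is recorded during continuous pattern
reversal, so wrap-around approximates the continuation better than zero-
or mirror-padding) and structurally essential — periodization is what
makes level $d$ hold exactly $256/2^d$ coefficients, so the transform is a
$256 \to 256$ orthogonal map. Orthogonality gives the two invariants the
package tests to $10^{-8}$ relative error on every supported wavelet:
Parseval ($\sum x_t^2 = \sum c_i^2$) and perfect reconstruction (the
inverse of the analysis step is its adjoint). Subset reconstruction —
inverse-transforming with all coefficients outside a kept set zeroed — is
then linear in the kept set, which the greedy selection below exploits.

One analysis step maps the current approximation $a$ (length $n$) to

$$A_k = \sum_{m=0}^{L-1} h_m\, a_{(2k + L/2 - m) \bmod n},$$

with the detail branch using the quadrature-mirror filter
$g_k = (-1)^{k+1} h_{L-1-k}$. The $L/2$ phase offset is the convention of
the standard `per` mode; test fixtures include coefficient vectors frozen
from an independent reference implementation of that mode.

The decomposition depth is $\lfloor \log_2(256/(L-1)) \rfloor$ for an
$L$-tap filter — the usual rule that stops the cascade before the filter
support exceeds the signal — with one deliberate exception: haar is capped
at level 7, so its deepest detail band splits the record into a 0–75 ms
cell containing P50 and a 75–150 ms cell containing N95.

Twenty mother wavelets are supported: haar, db2–db8, sym2–sym8, coif1–2
and fk4/6/8. Their scaling filters are the standard published orthonormal
filter banks. The Fejér–Korovkin filters are constructed in-package by
spectral factorization of the Fejér–Korovkin kernel's half-band
approximation (Nielsen 2001): the squared magnitude response is the kernel
convolved with the ideal half-band indicator — which satisfies the QMF
power-complementarity identity automatically — renormalized to place a
zero at $\pi$, then factored into its minimum-phase root and polished to
machine-precision orthonormality. The derived fk4 agrees with the commonly
tabulated coefficients to their printed precision.

## Index windows

Level-$d$ coefficients tile the 150-ms record uniformly: position $k$
(1-based) covers $[(k-1)w, kw]$ ms, $w = 150 \cdot 2^d/256$. Reported
integer bounds use round-half-to-even, which reproduces every printed
window simultaneously (37.5→38, 112.5→112, 56.25→56, 75→75). Frequency
bands are the ideal dyadic splits $[f_s/2^{d+1}, f_s/2^d]$ for details and
$[0, f_s/2^{d+1}]$ for the approximation, reported with
round-half-away-from-zero (giving 13/27/53 Hz at $f_s = 1700$). So the
flagship macular cone index D6-2 reads: detail level 6, second time cell —
38–75 ms, 13–27 Hz, squarely over P50. These integer conventions affect
*reporting only*; all computation uses exact bounds.

## Energy-to-entropy screening

For coefficients $c_i$ of a band (or of the full decomposition),
$E = \sum c_i^2$ and $H = -\sum p_i \ln p_i$ with $p_i = c_i^2/E$. The
ratio $E H^{-1}$ rewards wavelets that capture much power in few
coefficients. Natural logarithms are used (the choice of base rescales
every ratio identically, so the argmax is base-invariant). $H$ is exactly
0 for a point mass and $\ln N$ for $N$ equal magnitudes; an all-zero band
or a point-mass single-coefficient band makes the ratio undefined and the
recording is flagged `NA` and excluded from averages rather than
propagated.

Ratios are averaged recordings → participant → cohort; the two-stage
average matters because participants contribute unequal recording counts
(the test suite asserts the two orders genuinely differ on unbalanced
data). Bootstrap CIs (percentile, default 10,000 resamples) resample
participants — the participant is the independent unit — though a
recording-level variant is exposed as an option. Per band, the wavelet
with the highest mean ratio is retained. Exact ties (which occur: db2 and
sym2 have identical filters) break toward shorter filters, then toward
the symlet family — the symmetric, near-linear-phase design that
minimizes phase distortion of peak timing — then by name. Callers can
force inclusions; the canonical analysis forces haar (for its level-7
split) and coif1 (family representation). Note that bands beyond a
wavelet's depth simply do not exist for it: coif2 or db8 (depth 4) never
compete at D6, and their D6 ratios are reported as missing, not invented.

## Feature statistics

Features are the squared coefficients at detail levels D4..Dmax plus the
deepest approximation. D1–D3 cover >100 Hz, outside the 1–100 Hz
acquisition band-pass, and carry only noise; shallower approximations
duplicate the frequency content of retained details. With the six
canonical wavelets this yields exactly 192 candidate features (32 per
wavelet). Recordings are averaged within participant before testing, so
repeated measures cannot masquerade as sample size.

Group comparison uses the Mann–Whitney U with the orientation "normal
greater": $U$ counts cross-group pairs in which the normal value exceeds
the patient value (ties half), so $\mathrm{CLES} = U/(n_1 n_2)$ is
directly the probability that a random normal observation beats a random
patient observation, and is *identical* to the ROC AUC — the package
computes AUC by explicit pair counting in the benchmark module and
asserts the identity to $10^{-12}$. The z-statistic uses the normal
approximation with midrank tie correction and no continuity correction
(ties are rare in continuous energies; the p-values match
`wilcox.test(exact = FALSE, correct = FALSE)`). Effect size is
$r_{es} = |z|/\sqrt{N}$. FDR control is Benjamini–Hochberg at
$\alpha = 0.05$ via `p.adjust`, which the suite checks against the raw
step-up definition. Both $r_{es}$ and CLES are invariant under monotone
transforms of the feature values, so the energy-vs-amplitude scaling of
features is immaterial to ranking.

Redundancy pruning visits features in descending $r_{es}$ (ties:
descending CLES, then name) and keeps a feature only if its absolute
Spearman correlation with every already-kept feature is ≤ 0.9 — i.e. of a
redundant pair, the weaker discriminator is removed. The visiting order
makes the pairwise rule deterministic. Spearman correlations are computed
across participants (the feature table's unit). A constant feature has no
defined correlation and is treated as uncorrelated. One subtlety worth
recording: chains with $|\rho_{12}|, |\rho_{23}| > 0.9$ force
$|\rho_{13}| \gtrsim 0.62$ (rank correlation matrices are positive
semidefinite), so the "keep both endpoints" outcome exists only in a
narrow geometric regime; the tests construct it explicitly.

## Minimal reconstruction

For each canonical peak the question is: which *single* coefficient's
inverse transform preserves this peak? Peaks are measured as the window
extrema — N35 the minimum on 20–45 ms, P50 the maximum on 40–70 ms, N95
the minimum on 75–130 ms, ties to the earliest time. These windows are a
package decision (configurable): they bracket the canonical latencies
with margins consistent with normal morphology. Amplitude is the signal
value at the extremum; the error of a candidate set is
$\mathrm{MAE}_V \times \mathrm{MAE}_T$ (µV·ms) averaged over the normal
cohort's recordings (recording-level, not participant-averaged — every
trace must be reconstructible). The product form means a candidate can
reach zero through the time factor alone on the discrete grid, so
candidates are ordered by (weighted, amplitude MAE, time MAE, level,
position): exact self-reconstruction dominates coincidental zero
products. sym2 is the default reconstruction wavelet — symmetric,
near-linear phase, and shaped like the PERG deflections themselves.

The greedy step retains the best single index, then tries pairing it with
each of the next four best singles; the best pair replaces the single only
if it *strictly* lowers the weighted MAE and by at least 40%. The
strictness matters in the degenerate case: when the single already
achieves zero (single-atom cohorts), zero-to-zero is not an improvement
and the single is kept — the test suite builds such atom cohorts and
requires the generating index back, exactly, with zero error.

On synthetic normal cohorts the selection recovers the published
structure: N95 chooses the detail/approximation pair D6-3 + A6-4 (the
detail pins the timing, the approximation the amplitude), and the P50 set
contains the central-time low-frequency detail D6-2 — in our simulations
the timing-precise D4-6 can narrowly win the single stage, with D6-2
entering through the augmentation rule, so the property tested is that
the chosen *set* contains a level 5–6 detail overlapping 40–70 ms.

## Benchmarking and outliers

Benchmarks are participant-level: each participant's recordings are
averaged, then the index and the clinical markers are compared by Pearson
correlation (normals only), ROC/AUC, $r_{es}$ and Tukey summaries.
Tukey quartiles use type-7 linear interpolation — stated explicitly
because the 1.5 IQR fences inherit the convention. The outlier rule is
one-sided by design (only suspiciously *large* energies are artifacts of
interest) and leave-self-out: each value is compared against the mean and
SD of the remaining values, so a single extreme point cannot inflate the
SD enough to mask itself. Combined metrics (e.g. D6-2 with A6-3) use the
arithmetic mean of the two energies.

## The synthetic generator

Each trace is
$s(t) = -a_{N35} g(t; 35, 6) + a_{P50} g(t; 50, 8) - a_{N95} g(t; 95, 12)
+ \varepsilon(t)$ with unit-height Gaussians $g$, default amplitudes
1/4/5 µV, and iid noise of 0.2 µV on the 256-point grid. The widths place
>95% of signal energy inside the 1–100 Hz hardware band-pass. Because the
bumps overlap, the *true* extrema shift from the nominal centers (the
closed-form mixture puts N35 at 31.6 ms); the peak-measurement tests
compare against fine-grid evaluation of the mixture, not against the
nominal centers. Each participant draws one multiplicative log-normal
gain (log-SD 0.25, mean 1 — roughly the 25% between-subject amplitude
variation typical of evoked potentials; multiplicative so amplitudes stay
positive) shared across their recordings (default 4, alternating RE/LE).
mpIRD participants have $a_{P50}$ scaled by 0.3 and $a_{N95}$ by 0.6 —
pronounced macular cone loss with secondary ganglion-cell involvement.

What the generator does *not* emulate: implicit-time delays under
disease, 50 Hz interference, inter-sweep correlation, age effects on
amplitude, eye asymmetries (an optional per-eye gain exists to exercise
the eye-partition views), or the heavy-tailed artifact structure of
clinical recordings. Passing tests therefore demonstrate that the
pipeline recovers *known* structure of this form — attenuation expressed
in central-time low-frequency energy — not that clinical effect sizes
will match.

The CLES recovery check runs the full pipeline on ten cohorts of 40 + 40
participants and compares the top central-time D6 feature's CLES against
a 10,000-draw Monte-Carlo oracle that simulates participant-level feature
values directly (same generative process, no feature-table or rank
machinery), requiring agreement within three binomial standard errors
$\sqrt{p(1-p)/40}$.

## Problem sizes and determinism

The test suite exercises: 100 random traces × all 20 wavelets for the
transform invariants; 200 random small samples for the U/CLES/AUC
identities; 400 grid-sampled p-vectors for the FDR check; 20 random
single-atom cohorts for the selection; and ten 40 + 40-participant
cohorts for parameter recovery. All randomness flows through explicit
seeds (cohorts are bit-reproducible from `cohort_config(seed = )`;
`run_pipeline` writes the seed into its manifest), and the pipeline's
outputs are byte-identical across reruns of the same configuration.

## Known limitations

* Boundary handling is periodized only; other extension modes are
  rejected by design, because the dyadic coefficient counts and exact
  index↔window tiling are load-bearing for the whole analysis.
* The DWT phase convention follows the standard `per` mode; a different
  implementation with a different subsample phase would shift which
  position index covers a given peak by at most one cell.
* Approximation coefficients are addressable for reconstruction only at
  the deepest level (shallower approximations are linear combinations of
  retained details and would double-count energy).
* The Mann–Whitney p-values are asymptotic; at very small group sizes
  (< ~8 per group) exact tests would differ, though ranking by effect
  size is unaffected.
* `eye_partition("worst_p50n35")` relies on peak measurement and thus
  inherits its fragility on flat traces — the very motivation for the
  energy indices.
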