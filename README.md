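# pergdwt

Discrete wavelet analysis of pattern electroretinogram (PERG) recordings.

The PERG is the retina's response to a reversing checkerboard. Its clinical
reading rests on three canonical components — a negative deflection near
35 ms (N35), a positive peak near 50 ms (P50, the macular cone marker) and a
negative deflection near 95 ms (N95, the retinal ganglion cell marker) — and
on the amplitude differences |P50−N35| and |N95−P50|. In macular-predominant
inherited retinal disease (mpIRD: cone-rod dystrophy, macular dystrophy,
Stargardt disease) the P50 response collapses, but flattened traces make the
conventional peak measurements unreliable. `pergdwt` replaces them with
time-frequency *energy indices*: each 256-sample, 150-ms trace (1700 Hz) is
decomposed with a periodized orthogonal discrete wavelet transform, every
coefficient `c` at detail level `d`, position `k` is squared into an energy
`c²` covering a known window — time `[(k−1)·w, k·w]` ms with
`w = 150·2^d/256`, frequency `[fs/2^(d+1), fs/2^d]` Hz — and the indices are
carried through a full statistical pipeline:

1. **Mother-wavelet screening.** 20 candidates (haar, db2–db8, sym2–sym8,
   coif1–2, fk4/6/8) ranked per sub-100 Hz band (D4, D5, D6, A5, A6) by the
   energy-to-entropy ratio `E·H⁻¹`, where `E = Σc²` and
   `H = −Σ pᵢ·ln pᵢ` with `pᵢ = cᵢ²/E`, averaged recordings → participant →
   cohort with participant-level bootstrap CIs.
2. **Feature statistics.** Energies at D4..Dmax plus the deepest
   approximation, averaged within participant; Mann–Whitney U per feature
   (normal vs mpIRD), Benjamini–Hochberg FDR, effect size `r_es = |z|/√N`,
   common-language effect size `CLES = U/(n₁n₂)`, and greedy Spearman
   pruning at |ρ| > 0.9.
3. **Minimal reconstruction.** Per canonical peak, the single coefficient
   whose lone inverse DWT best preserves the peak's amplitude and implicit
   time across the normal cohort (weighted MAE = amplitude MAE × time MAE,
   µV·ms), augmented by a second coefficient only if it cuts the weighted
   MAE by ≥ 40%.
4. **Benchmarking.** Selected indices vs |P50−N35| / |N95−P50|:
   participant-level Pearson correlations, ROC/AUC by pair counting
   (identical to CLES by construction), Tukey summaries, and a one-sided
   leave-self-out >4 SD outlier rule.

A synthetic cohort generator (three Gaussian bumps per trace, per-participant
multiplicative gain, attenuated P50/N95 in the patient group, white noise)
emulates the statistical structure of clinical PERG data so every stage runs
and is testable with no external dataset.

## Worked example

```r
library(pergdwt)

cfg    <- cohort_config(n_normal = 20, n_mpird = 20, seed = 1)
cohort <- preprocess_cohort(generate_cohort(cfg))

tab  <- build_feature_table(cohort, c("haar","sym2","sym4","db4","coif1","fk4"))
st   <- rank_features(feature_stats(tab))
kept <- prune_correlated(tab, st)

normal <- cohort$meta$diagnosis == "normal"
sel <- select_minimal_indices(
  perg_cohort(cohort$meta[normal, ], cohort$samples[normal, ]), "sym2")
bench <- benchmark_indices(cohort, indices = "D6-2")
```

On this simulated cohort (40 participants, 160 recordings) the run prints:

```
features: 192   kept after pruning: 100

N35 -> D4-4          (weighted MAE 0.242 uV.ms)
P50 -> D4-6 + D6-2   (weighted MAE 1.785 uV.ms)
N95 -> D6-3 + A6-4   (weighted MAE 1.187 uV.ms)

  metric    auc    r_es   cles     index  marker  r_corr
    D6-2  1.000   0.855  1.000      D6-2 p50_n35   0.986
 p50_n35  0.990   0.838  0.990      D6-2 n95_p50   0.989
 n95_p50  0.983   0.825  0.983
```

Reading this: the six wavelets yield 192 candidate energy features, of which
100 survive redundancy pruning. The greedy reconstruction localizes each
canonical peak to one or two sym2 coefficients — for P50 a central-time
low-frequency detail pair including D6-2 (38–75 ms, 13–27 Hz), for N95 the
pair D6-3 + A6-4 — and the D6-2 energy separates the groups at least as well
as the conventional macular cone marker |P50−N35| (AUC 1.000 vs 0.990) while
tracking it almost perfectly in normals (r = 0.986). The attenuation built
into the simulated patient group is strong, so absolute AUCs here are higher
than one should expect on clinical data; the qualitative ordering is the
point.

## Command line

```sh
Rscript inst/cli/pergdwt.R run-all  --config cfg.yaml --seed 1 --out results/
Rscript inst/cli/pergdwt.R simulate --seed 1 --out cohort.csv
```

`run-all` writes `screening.csv`, `feature_table.csv`, `feature_stats.csv`,
`selection.csv`, `benchmark.json` and a reproducibility `manifest.json`.

See `vignettes/pergdwt-methods.Rmd` for the model, the numerical
conventions (periodization, rounding of reported windows, tie-breaks) and
the design decisions.
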