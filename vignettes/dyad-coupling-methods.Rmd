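---
title: "Methods: multimodal speaker-listener coupling from dyadic PPG, speech and emotion streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal speaker-listener coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The analysis in one paragraph

Two people in conversation do not only exchange words: their heart rhythms,
speech prosody and reported emotions co-vary, and the *direction* of that
co-variation — who leads and who follows — carries information about the
interaction. `dyadsync` implements a pipeline that starts from raw wrist
photoplethysmography (PPG) at 64 Hz, speaking-segment annotations and
5-second arousal/valence annotations for a dyad; extracts beat-to-beat (RR)
interval series, a PPG-derived respiration signal, windowed
information-theoretic features and a standard heart-rate-variability (HRV)
panel; cuts the conversation into speak-listen phase segments; estimates
per-segment lagged cross-correlation between the two participants' RR
dynamics; classifies each segment by the sign of the peak lag (who led) and
the sign of the peak correlation (in-phase vs inverse coupling); and
summarizes features and emotion-state distributions by those classes with
nonparametric group statistics. A seeded synthetic dyad generator with known
ground truth makes every stage testable without access to any real
recordings.

## Signal conditioning and beat detection

Raw PPG is band-pass filtered at 0.5–5 Hz with a 4th-order Butterworth
design applied forward-backward (`bandpass_ppg()`): zero phase shift, an
effective 8th-order magnitude response. The mean is removed before
filtering (the pass band excludes DC) and the signal is padded by odd
reflection so the forward-backward pass has no edge transients. Pulse peaks
are local maxima separated by at least 0.4 s — the spacing of a 150 bpm
ceiling, conservative for seated conversation — with the taller peak winning
any conflict window (`detect_peaks()`).

The resulting RR series is cleaned with a decision-based rank-order median
(SDROM-style) filter (`clean_rr_sdrom()`): an interval deviating from its
5-beat running median by more than 20% of that median is replaced by the
median and flagged. The window and threshold are package defaults chosen to
flag textbook ectopic-like jumps (40–100% deviations) while passing normal
variability; both are arguments. The filter is idempotent. Cleaned intervals
are interpolated linearly to the 64 Hz frame grid (`interpolate_rr()`), each
interval anchored at the beat that closes it, edges held constant. Linear
interpolation was chosen over spline for monotone boundedness (a cubic
spline can overshoot below zero on pathological inputs); we evaluated a
natural spline and found only marginally better lag recovery.

Respiration (`derive_respiration()`) fuses the three standard PPG
respiratory mechanisms — baseline wander, pulse-amplitude modulation
(analytic-signal envelope of the filtered PPG) and respiratory sinus
arrhythmia (the RR track) — each band-passed to 0.1–0.7 Hz, z-normalized and
averaged. The respiratory band-pass runs on a 4 Hz decimated timeline: a
Butterworth band-pass with a normalized low edge of 0.003 (0.1 Hz at 64 Hz)
is numerically ill-conditioned under forward-backward filtering, and
decimating first is standard practice. The respiration rate is the dominant
Welch spectral peak of the composite within 0.1–0.7 Hz (60-s windows, 50%
overlap). `regress_out()` provides the per-participant ordinary
least-squares adjustment of per-segment features for heart-rate and
respiration covariates, returning residual plus participant mean so the
feature keeps its scale; adjustment is per participant so between-subject
variance does not leak into the fit.

## Entropy features

All windowed entropies use a single 10-bin histogram whose edges span the
recording (`global_bin_edges()`), so windows are comparable within a
session, and natural logarithms throughout. Shannon entropy is
$-\sum_i p_i \ln p_i$; Rényi entropy
$H_\alpha = \ln(\sum_i p_i^\alpha)/(1-\alpha)$ over occupied bins for
$\alpha \in \{-5,-3,-1,1,3,5\}$, with $\alpha = 1$ returning the Shannon
limit. Sample entropy (`sample_entropy()`) is $-\ln(A/B)$ with templates of
length $m = 2$, Chebyshev tolerance $r = 0.2\,\mathrm{SD}$ (the relative
convention), self-matches excluded; degenerate (zero-variance) windows are
flagged missing rather than 0 or $\infty$, and missing values are excluded
pairwise downstream. The implementation is verified against a brute-force
$O(n^2)$ template count to $10^{-12}$.

Diffusion entropy analysis (`dea()`) reduces a series to events — frames
where the value lies outside the ±1 SD stripe around the series median —
builds diffusion trajectories as moving-window event counts, and estimates
the entropy $S(l)$ of the displacement distribution at window lengths $l$ on
a dyadic grid. $S(l)$ uses the differential form
$-\sum_i p_i \ln p_i + \ln h$ with a Freedman-Diaconis bin width $h$ floored
at 1 (displacements are integer counts); the $\ln h$ term is essential —
without it the FD width's $\sqrt{l}$ growth exactly cancels the entropy
growth. The scaling exponent $\delta$ is the least-squares slope of $S(l)$
against $\ln l$ over $l \in [10, \max(32, n/100)]$, capped at 1, and the
complexity index is $\mu_r = 1 + 1/\delta$, saturating at $\delta = 1$ for
$\mu_r \ge 2$. The upper fit bound is $n/100$ rather than a larger fraction
because beyond it the overlapping windows leave too few independent
displacement samples and the empirical entropy is biased downward; the
bound was validated against the two analytic anchors — $\delta = 0.5$ for
i.i.d. series and $\delta \to 1$ (capped) for ballistic or persistent
series — which the test suite checks, together with the
shuffling-destroys-correlations property. `msdea()` repeats the analysis on
block-averaged coarse-grained series at scales 4, 8, 16, 32 and 128;
"scale 1" is the raw series and supplies the per-segment `delta_scale1` /
`mu_r_scale1` columns.

One caveat worth stating: on a 64 Hz RR track that is *interpolated* from
~1.25 Hz beats, the series is locally linear, events cluster into long runs
and $\delta$ frequently saturates at 1. That is the correct answer for such
an input, not an estimator defect; comparisons across segments should keep
this in mind.

## HRV panel

`hrv_time_domain()` reports AVNN, SDNN (sample SD), RMSSD, pNN50 and SEM.
`hrv_freq_domain()` detrends the RR track, resamples to 4 Hz and averages
Hann-windowed 60-s Welch segments at 50% overlap; band powers integrate the
one-sided PSD over VLF 0.0033–0.04, LF 0.04–0.15 and HF 0.15–0.4 Hz (the
Task-Force edges; the PSD is interpolated at the band boundaries so the
narrow VLF band is not truncated by the frequency grid). Normalized LF/HF
powers are percentages of LF+HF and sum to 100 by construction;
VLF+LF+HF never exceeds the total power. Segments shorter than 60 s fall
back to a single periodogram and are flagged; in the pipeline,
frequency-domain members are only computed for segments of at least 60 s,
since VLF/LF are undefined on shorter stretches.

`poincare()` computes SD1 as the *uncentered* dispersion of successive
differences, $\mathrm{SD1} = \mathrm{RMS}(\Delta RR)/\sqrt{2}$, so the
identity $\mathrm{SD1} = \mathrm{RMSSD}/\sqrt 2$ holds exactly (the centred
and uncentered conventions differ only by the mean successive difference,
which is negligible in practice but would break the identity at machine
precision); SD2 follows from $2\,\mathrm{SDNN}^2_{pop} - \mathrm{SD1}_c^2$,
floored at zero. `dfa()` is standard detrended fluctuation analysis with
box ranges 4–11 ($\alpha_1$) and 12–64 ($\alpha_2$) beats. Note that DFA1
at boxes as small as 4 beats carries a known finite-size upward bias: for
white noise $E[F^2(s)] = \sigma^2 (s^2-4)/(15 s)$, so the fitted
$\alpha_1$ is ~0.62 rather than 0.5, asymptoting to 0.5 only at larger
boxes. We keep the conventional estimator and document the bias; the tests
assert the unbiased facets ($\alpha_2 \approx 0.5$ on white noise,
$\alpha_1 \approx 1.5$ on integrated noise).

## Speech features

`pitch_ncf()` is a normalized-cross-correlation pitch tracker: per 40-ms
frame, the NCF is evaluated over lags spanning 50–300 Hz; frames whose NCF
peak is below 0.3 are unvoiced. Among local NCF maxima within 0.02 of the
global maximum the shortest lag wins (the standard octave-error guard), and
the lag is refined parabolically. The frame-rate track is resampled to the
64 Hz timeline by nearest neighbour. `align_pitch()` corrects window-induced
timing offsets by shifting the track within ±1 s to maximize the correlation
of its voicing indicator with the intensity trace; `gate_by_speaker()`
zeroes pitch outside the speaker's own mask. `pitch_window_stats()`
summarizes voiced samples only — windows with fewer than 50 voiced samples
are flagged missing, since unvoiced zeros would otherwise dominate every
moment — reporting mean, SD, adjusted Fisher-Pearson skewness, non-excess
kurtosis (normal = 3) and Shannon entropy over 10 fixed-width bins spanning
50–300 Hz (fixed, so pitch entropy is comparable across speakers).

## Phase segmentation and coupling

`segment_phases()` maps the two binary speaking masks to a frame-wise state
(A speaks/B listens, B speaks/A listens, both, neither), takes maximal runs
as candidate segments, and absorbs runs shorter than 5 s (one emotion
annotation period) into the longer neighbouring run until every segment
meets the minimum. Simultaneous segments must be at least 90% pure
(speaker mask 1, listener mask 0); backchannel-heavy stretches below that
purity are retained in the table for exact session coverage but flagged out
of analysis. `within_participant_pairs()` pairs each participant's
consecutive speaking and listening intervals, trimmed to equal length.
`dominant_emotion()` attaches the modal frame-level label per segment, ties
broken toward the longer contiguous run, then the earlier label.

`xcorr_unbiased()` detrends both segment tracks linearly, z-normalizes with
the population SD (so the autocorrelation of any track at zero lag is
exactly 1) and evaluates
$r(k) = \frac{1}{N-|k|} \sum_t \tilde x(t)\,\tilde y(t+k)$ over
$k \in [-K, K]$. Positive $k$ means the first participant's signal leads.
The curve is clipped to $[-1, 1]$ (the unbiased scaling can marginally
exceed 1 on strongly periodic segments). `peak_and_classify()` takes the lag
maximizing $|r(k)|$ — the signed value is retained, because segments are
classified by both lag sign (POS/NEG/ZERO; ZERO is excluded from lag
contrasts) and correlation sign — with ties broken toward smaller $|k|$,
then negative $k$. `couple_session()` applies this per segment with a
default ±5 s search, *capped at a quarter of the segment length for every
segment*: the $1/(N-|k|)$ scaling inflates the estimator variance as the
overlap shrinks, and on short segments boundary-lag spurious peaks would
otherwise dominate. This cap generalizes the shrink rule that would apply
only to segments shorter than $2K$; segments where the cap bites are
flagged. A corollary worth knowing: a lead-lag of $\tau$ seconds is simply
not identifiable in a segment much shorter than $4\tau$.

## Group statistics

`kruskal_wallis()` wraps the rank test with the chi-square reference (the
form used for all reported tables) and adds `p_exact`, the exhaustive
permutation tail probability, for total samples of 10 or fewer — at such
sizes the chi-square approximation can deviate from the exact tail by more
than 0.1. `bonferroni()` multiplies by the family size (one contrast
table = one family) and clips at 1. `chi_square_emotion()` tests a POS/NEG
count pair against an equal split (1 df, no continuity correction),
reporting an exact binomial p alongside for totals under 10.
`pearson_test()` is the t-test on the correlation coefficient.
`build_contrast_table()` joins per-segment, per-participant feature values
with coupling classes — both participant orderings are enumerated, so each
segment contributes one directed observation per participant, the second
participant's lag class negated — and reports median, IQR (type-7
quantiles), group sizes, raw and Bonferroni-adjusted p, with 0.05–0.1
flagged as a trend. `build_emotion_table()` counts POS/NEG segments per
dimension × perspective × state with column-wise percentages, per-cell
chi-square tests and pooled totals; `emotion_association_test()` is the
omnibus Pearson chi-square of the 2 × states table, the single test the
per-state cells decompose.

## The synthetic dyad generator

`simulate_dyad()` builds a complete session with known ground truth; its
defaults are the study conditions the tests run under, chosen once:

* **Timeline**: 600 s at 64 Hz — a 10-minute debate.
* **Cardiac dynamics**: each participant's latent RR track is
  $60/\mathrm{HR}$ (75 and 72 bpm) modulated by an LF sinusoid at a
  participant-specific frequency in 0.08–0.12 Hz (depth 3%) and an HF
  sinusoid at the respiration rate 0.3 Hz (depth 2.5%), plus broadband
  noise of SD 0.05 s smoothed over 1 s. Two of these choices are
  load-bearing. The noise is band-limited below the ~0.6 Hz Nyquist of
  beat-interval sampling: frame-level white noise would be destroyed by the
  two participants' asynchronous beat times and the injected lag would not
  survive into the RR series. And the LF frequencies are jittered per
  participant so that two *uncoupled* participants, each carrying a
  coherent 0.1 Hz rhythm, decorrelate over a session instead of producing
  spurious sinusoid-locking correlations.
* **Coupling**: participant 2's track is
  $(1-|g|)\,\mathrm{own} + g\,\mathrm{rr}_1(t - \mathrm{lag})$ with gain
  $g = 0.7$ and lag $+2$ s; a negative gain mirrors the fluctuations around
  participant 1's baseline (inverse coupling with positive intervals
  preserved). The lag sign switches per speaking turn by default
  (piecewise-constant regimes, giving each session both leading and
  lagging episodes); `regime_switching = FALSE` holds one regime, which is
  the mode used when recovery of `sign(couple_lag)` itself is measured.
  Beat times integrate the latent track; `rr_to_ppg()` renders Gaussian
  pulses (SD 60 ms) with 10% respiratory amplitude modulation, respiratory
  baseline drift and additive noise, closing the loop so peak detection is
  testable against known beat times.
* **Turn-taking**: alternating turns, exponential with mean 25 s floored at
  18 s, overlapping speech inserted at 20% of boundaries; brief
  interjections are represented by those overlaps rather than by turns.
  The floor reflects moderated-debate exchanges and doubles as the
  identifiability constraint above: with a ±2 s injected lag, segments must
  be several times that long for the lag to be observable at all.
* **Emotions**: per 5-s window, arousal and valence are drawn from a
  distribution conditioned on the current lag regime; the default bias ties
  states 4–5 to the positive regime and 1–2 to the negative regime
  (`emotion_bias_null()` removes the association). Partner and external
  perspectives are noisy copies of self with one-step confusion
  probability 0.2.

What the generator does *not* emulate: motion artifacts and PPG dropouts,
respiratory rate drift, non-stationary heart-rate trends, realistic audio
waveforms (pitch tracks are generated directly), multi-annotator
disagreement structure, or coupling that varies continuously in strength.
Passing tests therefore demonstrate that the estimators recover what they
claim under clean, stationary conditions with known ground truth — not that
any particular real dataset satisfies those conditions.

## Validation experiments the test suite runs

* Sample entropy equals the brute-force oracle to $10^{-12}$ on 50 seeded
  windows.
* DEA: mean $\delta = 0.5 \pm 0.05$ over 20 i.i.d. Gaussian series of
  length $10^5$; $\delta$ capped at 1 on ballistic input; shuffling restores
  $\delta \approx 0.5$.
* HRV identities: $\mathrm{SD1} = \mathrm{RMSSD}/\sqrt 2$ to $10^{-12}$;
  $\mathrm{LF}_{norm} + \mathrm{HF}_{norm} = 100$;
  VLF+LF+HF ≤ total power.
* Coupling recovery: over 100 seeded 600-s sessions at gain 0.7 with a
  constant regime, the per-segment lag sign is recovered in ≥95% of
  simultaneous segments and the median absolute lag error is ≤1 s
  (measured on the interpolated RR tracks the coupling module consumes;
  the PPG → peak-detection round trip is validated separately).
* Small-sample rank test: `p_exact` matches an independent exhaustive
  enumeration at N = 8; the 5-vs-25 count split gives chi-square
  p < 0.001.
* End-to-end emotion recovery: with the default bias, the omnibus
  lag-regime × arousal association is detected (p < 0.05) in ≥90% of 100
  seeded runs; with the null bias the false-positive rate is ≤10%.

Problem sizes in the routine suite (series lengths, seed counts, session
durations) are the package's chosen test scale; the experiments above are
the full-scale ones.

## Known limitations

* The directionality analysis assumes one dominant, piecewise-constant
  lead-lag per segment; continuously varying or bidirectional coupling is
  summarized by a single peak and can be misclassified near regime
  boundaries.
* Lag recovery degrades sharply on segments shorter than about four times
  the true lag; such segments are analysed (with a shrunken search range)
  but contribute noise.
* $\delta$/$\mu_r$ on interpolated RR tracks saturates readily (see above);
  multiscale values at coarse scales are more discriminative.
* DFA $\alpha_1$ carries the documented small-box bias; compare values only
  against estimators with the same box convention.
* The per-segment frequency-domain HRV panel requires ≥60 s segments;
  shorter conversational exchanges have no VLF/LF estimates by design.
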