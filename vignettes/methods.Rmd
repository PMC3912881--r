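---
title: "Methods: LF/HF heart rate variability and questionnaire inference for performance-stress studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LF/HF heart rate variability and questionnaire inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvstress)
library(dplyr)
```

## The scientific problem

Performing under evaluation — an audition, a recital — elevates sympathetic
arousal, and the balance between sympathetic and parasympathetic influence
on the heart can be indexed from the electrocardiogram. The beat-to-beat
(R-to-R) interval fluctuates with breathing and autonomic tone; decomposing
its fluctuation into a low-frequency band (LF, 0.04–0.15 Hz, mixed
sympathetic and other influence) and a high-frequency band (HF, 0.15–0.4 Hz,
mainly respiratory sinus arrhythmia / parasympathetic) gives the LF/HF power
ratio, a widely used — and widely debated — index of sympatho-vagal balance.
This package implements the full quantitative analysis of a within-subjects
performance-stress study: LF/HF estimation from RR series, state-anxiety
(STAI Form Y1) and simulation-evaluation questionnaire scoring, and the
matching inference battery (one-sample Wilcoxon signed-rank against a scale
midpoint, paired t, 3×2 within-subjects ANOVA), together with a synthetic
data generator so that every stage can be validated by parameter recovery
without any recorded human data.

## The RR signal model

The generator works in the beat domain: the interval that starts at beat
time $t$ is

$$\mathrm{RR}(t) = \mu + a_{LF}\sin(2\pi f_{LF} t) + a_{HF}\sin(2\pi f_{HF} t) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

in milliseconds, and the next beat follows $\mathrm{RR}(t)/1000$ seconds
later. We deliberately do not use an integral-pulse (IPFM) model: treating
RR as a signal sampled at beat times matches how the analysis side treats
it (a tachogram to be interpolated), and it keeps the ground truth
analytic — a sinusoidal modulation of amplitude $a$ contributes exactly
$a^2/2$ ms² of power to its band, so the pipeline's recovered band powers
have closed-form targets. The price is realism: real HRV has broadband
spectra, respiratory frequency drift, and nonstationarity that a two-tone
model does not emulate, so passing recovery tests demonstrates correctness
of the *estimator*, not performance on real recordings.

Default parameters: mean RR 800 ms (75 bpm, a plausible resting adult
rate), $f_{LF} = 0.095$ Hz and $f_{HF} = 0.25$ Hz (band centers; 0.25 Hz is
a typical eupneic breathing rate), noise SD 10 ms. The amplitude-budget invariant
$a_{LF} + a_{HF} + \sigma < \mu$ guards against nonpositive intervals.

Ectopic beats are modelled as shorten/lengthen couplets — the selected
interval loses a fraction of its value and the next interval gains the same
absolute amount — so total elapsed time is exactly conserved. This is the
canonical premature-beat artifact that median filtering removes.

## The analysis pipeline

1. **Median filter (beat domain, kernel 5, replicate-padded edges).**
   Applied *before* interpolation: an ectopic is a one-or-two-beat
   excursion in the beat domain but smears across many samples once
   splined. The high-level pipeline applies it only when the data are
   expected to contain artifacts (in `run_study()`, when the design injects
   ectopics). The reason for not filtering unconditionally is measurable:
   at a ~1.25 Hz beat rate a kernel-5 median attenuates a 0.25 Hz
   HF modulation to roughly 0.31 of its amplitude (≈ 10× power loss), which
   would bias LF/HF upward severely when there is no artifact to remove.
2. **Cubic-spline resampling at 4 Hz.** A natural cubic spline through the
   (beat time, interval) knots, evaluated on a uniform 4 Hz grid — the
   standard transformation of the irregular tachogram into an evenly
   sampled series. The interpolant passes through every knot exactly.
3. **Zero-phase Butterworth band decomposition.** LF and HF components are
   obtained with 4th-order Butterworth bandpasses (design order in the
   MATLAB/Octave sense), applied forward–backward. Zero-phase application
   was chosen because windowed powers must be time-aligned with segment
   boundaries; a causal pass would delay the envelope by several seconds
   and bleed pre-performance power into the performance segment.
4. **Windowed band power.** Per 60 s window (30 s hop, 50 % overlap —
   ≥ 2.4 cycles of the lowest LF frequency per window), power is the mean
   squared component sample, and the ratio is LF/HF. Windows whose span
   intersects the first or last $1.5/f_{low} = 37.5$ s are discarded by
   default: Butterworth edge transients inflate power there. Powers are
   time-domain band powers (matching a filter-based description), not
   periodogram estimates.
5. **Segment means.** A window belongs to the segment containing its
   center, with half-open $[start, end)$ bounds so no window is counted
   twice at segment joins.

Measured on 300 s noise-free single-tone inputs, the pipeline recovers
band power within about 10 % of $a^2/2$ (the loss comes from sampling the
modulation at irregular beat times, which moves a little energy into
sidebands) and amplitude-ratio targets $(a_{LF}/a_{HF})^2$ within the same
margin — comfortably inside the 15 % tolerance used by the recovery suite.

### A note on median-filter repair accuracy

The repair test asks that ≥ 90 % of ectopic-corrupted beats be restored to
within 5 % of their clean values. A median filter can never return a value
closer to the truth than the median of the clean neighbourhood, so this
criterion is only meaningful when the clean signal's *own* kernel-median
stays within the 5 % band — i.e. when beat-to-beat modulation is small
relative to the tolerance. With $a_{HF} = 20$ ms on an 800 ms mean the HF
wiggle alone moves neighbouring beats by up to 5 % and the bound is
unattainable for any median filter; the repair fixtures therefore use
$a_{LF} = 20$, $a_{HF} = 10$, noise 5 ms, and assert the restorability
precondition explicitly before measuring repair (which then succeeds for
every corrupted beat).

## Questionnaire scoring

**STAI Form Y1**: 20 items on a 1–4 scale; reverse-keyed (anxiety-absent)
items are inverted ($r \mapsto 5 - r$) and the transformed items summed,
giving 20–80. The reverse-item set is a *configuration input* with a
documented default (the ten conventionally positively worded items:
1, 2, 5, 8, 10, 11, 15, 16, 19, 20): the instrument is under copyright and
its keying cannot be verified from a study description, so correctness must
not silently depend on a hard-coded list. Missing items are an error — no
imputation.

**Simulation-evaluation battery**: 19 items on a 1–5 agreement scale.
Descriptives per item use the midpoint convention for even-$n$ medians
(producing half-point medians such as 4.5) and the $n-1$ SD. The package
ships the published per-item summary table (both conditions, with `ns`
literals in the p column) as a fixture; `count_significant()` applies the
α = 0.05 counting rule to any such table, recovering the reported tallies
(12/19 and 13/19 items above the midpoint).

The synthetic Likert generator discretizes a logistic latent variable with
per-item location shifts through symmetric cuts at ±0.5 and ±1.5, so a zero
shift yields an exact midpoint median — a testable calibration point. The
STAI generator targets the *score* distribution (drawing each respondent's
total from a clamped rounded normal and spreading the excess across items)
because score-level mean/SD is the quantity such studies report; it makes
no claim about per-item covariance structure.

## Inference

**One-sample Wilcoxon signed-rank** (the non-parametric analogue of the
one-sample t-test, used because most items fail a Shapiro–Wilk normality
screen): differences from the hypothesized median are ranked by absolute
value with average ranks for ties; zero differences are removed (Wilcoxon's
convention — chosen over Pratt's to match mainstream practice; a different
handling can be layered on by the caller). The null distribution of the
positive-rank sum is computed *exactly* by convolution over the (doubled,
hence integer) ranks — algebraically identical to enumerating all $2^n$
sign assignments, including under ties — whenever $n_{\mathrm{eff}} \le 25$
with untied ranks, or $n_{\mathrm{eff}} \le 12$ regardless of ties. Beyond
that the tie-corrected normal approximation with continuity correction is
used (exact and approximate p agree within 0.01 at $n = 25$). The
two-sided p doubles the smaller tail, capped at 1. Tests default to
two-sided; the one-sided alternative is an explicit option.

**Paired t**: $t = \bar d / (s_d/\sqrt n)$ with $n-1$ df.

**Within-subjects ANOVA**: classical two-factor fully-within decomposition
with one observation per participant × cell. Each effect is tested against
its own participant-by-effect stratum: for the 3 (time) × 2 (condition)
study shape with $n = 7$ this yields the df structure (2, 12), (1, 6),
(2, 12). Uncorrected df are the default (reproducing how such designs are
conventionally reported); Greenhouse–Geisser ε-corrected p-values are
available as an option, with ε computed from orthonormalized effect
contrasts. Degenerate inputs (zero error mean square) flag F as undefined
rather than reporting nonsense; incomplete or unbalanced designs are
refused outright. No correction is applied across the 19 per-item tests by
default — fidelity to the single-test convention first; a caller wanting
family-wise control can `p.adjust()` the tidy output.

**Shapiro–Wilk** screening delegates to the standard implementation
(`stats::shapiro.test`), exposed behind a tidy wrapper.

## The synthetic study and its calibration

`study_design()` describes the full within-subjects layout: 7 participants,
two conditions (simulated vs real audition), three segments (baseline =
last 5 min of an induction session, pre-performance = the 5 min of
backstage waiting, performance = the audition itself; 300 s each by
default, the performance length being a fixed configurable stand-in for
"the entire audition"). The per-cell target LF/HF ratio matrix defaults to
the qualitative stress pattern of interest — elevated pre-performance
balance in both conditions, markedly higher before the real audition
(baseline 1.5/1.5, pre 3/6, performance 2/2) — and the generator achieves a
target $r$ analytically by holding $a_{HF}$ at 20 ms and setting
$a_{LF} = a_{HF}\sqrt{r}$. A lognormal per-participant-per-cell jitter
(SD 0.2 on the log scale) provides between-subject heterogeneity. STAI
targets default to means 32.29 (SD 7.39) and 37.43 (SD 7.09) for the
simulated and real conditions.

Calibration properties verified by the test suite, at the sizes stated:

- exact Wilcoxon p equals brute-force $2^n$ enumeration for $n \le 12$
  across 200 random tied/untied inputs;
- Wilcoxon at $n = 12$ and each ANOVA effect at $n = 7$ hold the nominal
  5 % level within [0.035, 0.065] over 2000 null replicates;
- spectral parameter recovery within 15 % on 300 s segments;
- the full pipeline on the default design recovers the designed maximum in
  the real/pre-performance cell and the (2, 12)/(1, 6)/(2, 12) df
  structure.

Simulation sizes (2000 replicates for type-I calibration, 300–800 s
recordings elsewhere) were chosen so Monte-Carlo error is a small fraction
of each tolerance band while the whole suite stays quick to run.

## Numerical and degenerate-input conventions

All times are seconds from recording start; intervals are milliseconds;
powers ms²; ratios dimensionless. Intervals outside 200–3000 ms are flagged
with a warning but never silently dropped (removal is the median filter's
job). Every generator is a pure function of its arguments including the
seed; composite generators derive component sub-seeds deterministically
from the master seed. Constant series: the spline and median filter pass
them through unchanged; the Wilcoxon errors when every value equals the
hypothesized median (zero removal leaves no information); Shapiro–Wilk and
the paired t error on zero variance; the ANOVA flags all-equal cells.
A window ratio is `NA`-flagged when HF power is exactly zero (possible only
for identically zero input, since filtered noise-free sinusoids still leak
infinitesimal power).

## Known limitations

- The two-tone RR model cannot probe robustness to broadband or
  nonstationary HRV spectra, respiratory drift, or real ectopy morphology;
  recovery results validate the estimator chain, not field performance.
- LF/HF itself is a contested index of sympatho-vagal balance; the package
  computes it, it does not defend it.
- The R-peak detector is a threshold-plus-refractory device for clean
  synthetic traces, not a clinical QRS detector.
- No Welch/AR spectral estimation, VLF band, or time-domain HRV suite
  beyond mean/SD of RR; no post-hoc pairwise comparisons or mixed-effects
  alternatives to the classical ANOVA.
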