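---
title: "Band ratios, aperiodic activity, and what ratio measures actually reflect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band ratios, aperiodic activity, and what ratio measures actually reflect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandratios)
```

## The question this package addresses

Frequency band ratios — mean power in a low band divided by mean power in
a high band, most famously the theta/beta ratio (TBR) — are widely used in
cognitive and clinical electrophysiology as if they quantified the
relative strength of two oscillations. That interpretation presumes that
power inside a canonical band is periodic power. Neural power spectra,
however, are the sum of band-limited periodic peaks *and* a 1/f-like
aperiodic component that contributes power at every frequency. A ratio of
band powers therefore responds not only to oscillatory power but to peak
center frequency, peak bandwidth, and — most importantly — to the slope of
the aperiodic component, which tilts power between any low and high band
simultaneously.

`bandratios` implements the machinery needed to make that argument
quantitative and testable: a generative spectral model, ratio measures, a
spectral parameterization that separates periodic from aperiodic activity,
systematic parameter sweeps, a synthetic resting-state cohort generator
with ground truth, and the bootstrap correlation statistics used to ask
which spectral parameters a ratio measure actually tracks.

## The generative model

A spectrum in log10 power is

$$P(f) = L(f) + \sum_n G_n(f) + \varepsilon(f),$$

with the aperiodic component $L(f) = b - \chi \log_{10} f$ (offset $b$,
exponent $\chi$; in linear power this is the $1/f^{\chi}$ form) and each
peak a Gaussian $G_n(f) = a_n \exp(-(f - c_n)^2 / 2 w_n^2)$ with center
frequency $c_n$ (Hz), power $a_n$ (au, height above the aperiodic
component), and bandwidth $w_n$ (Hz, the Gaussian width parameter).
$\varepsilon$ is independent normal noise per frequency bin with SD 0.005
au. Throughout the package, "bandwidth" means the Gaussian $w$, not the
full width $2w$; power is stored in log10 spacing, and linear power
$10^P$ is formed only where an operation demands it.

The default frequency axis is 1–35 Hz at 0.5 Hz resolution (69 bins,
endpoints included). Axes are generated by count rather than repeated
addition, so grid values carry no floating-point drift; this matters
because sweep tests compare slices of different grids bit for bit.

## Band ratios

Canonical bands are theta 4–8 Hz, alpha 8–13 Hz, beta 13–30 Hz. Two
conventions are fixed deliberately:

* **Inclusive edges.** The printed canonical definitions overlap at 8 Hz;
  we keep that literally, so the 8 Hz bin belongs to both theta and
  alpha. Users wanting half-open bands can supply custom `band()`
  definitions; the choice is visible in every result because band edges
  travel with the measure.
* **Linear-power averaging.** Band power is the mean of $10^P$ over the
  band's bins, matching absolute-power band measures; the ratio of two
  such means is then invariant to any offset shift (a constant in log10
  power multiplies both bands equally and cancels).

The default ratio set is theta/beta, theta/alpha, and alpha/beta. Ratios
are reported raw and log10-transformed; the log form is used for plotting
paired-sweep surfaces because ratio distributions are strongly skewed.

## Spectral parameterization

`fit_spectrum()` decomposes a spectrum into aperiodic parameters plus
Gaussian peaks. Default settings: peak width bounded to 1–8 Hz, at most 8
peaks, minimum peak height 0.1 au, relative detection threshold 2 SD of
the flattened spectrum, fixed (knee-free) aperiodic mode.

The algorithm is staged:

1. *Robust aperiodic seed.* OLS of log10 power on log10 frequency, then a
   re-fit using only the half of the bins with the lowest residuals —
   bins least contaminated by overlying peaks.
2. *Flattening.* Subtract the seed fit.
3. *Iterative extraction.* Repeatedly take the maximum of the flattened
   spectrum as a candidate peak; stop when its height falls below
   `max(min_peak_height, 2 × SD(flattened))` or the peak cap is reached.
   The width guess comes from the half-max crossing distance
   ($\sqrt{2\ln 2}\,w$ for a Gaussian), using the **shorter** side so a
   neighboring peak's shoulder cannot inflate it, clamped to the bounds.
   Each guess is subtracted before the next round.
4. *Joint peak refit.* All Gaussians are refit together against the
   flattened spectrum by bounded Levenberg–Marquardt least squares
   (`minpack.lm::nls.lm`); centers may move at most $2w$ from their
   guess, heights stay non-negative, widths stay within bounds.
5. *Aperiodic re-fit* on the peak-removed spectrum.

Stages 2–5 run twice: the second pass flattens against the improved
aperiodic estimate, which recovers peaks the peak-biased seed obscured.
A final bounded joint polish of the aperiodic parameters *together with*
all Gaussians then removes the residual coupling between the two
components; if the polish discards a peak that fell below the height
threshold, the aperiodic component is re-fit without it, so reported
aperiodic parameters never lean on discarded peaks. On noiseless
model-matched input this procedure recovers the generating parameters
essentially exactly ($r^2 \ge 0.999$); the test suite verifies, over a
randomized suite of 200 noiseless spectra with 0–3 well-separated peaks,
exponent recovery within 0.05 and center recovery within 0.25 Hz in at
least 99% of draws, and at the 0.005-au noise level, exponent within 0.1
and centers within 0.5 Hz with a failure rate below 5%.

Goodness of fit is the squared Pearson correlation between model and data
log10 power (the model is defined in log space), plus the mean absolute
log10 error. If the least-squares refit fails to converge the fit returns
the guess-stage parameters flagged `converged = FALSE` rather than
crashing.

Two width conventions deserve a note. The sweep tables simulate peaks
with bandwidths of 0.1–0.4 Hz, far below the 1 Hz fit lower bound; these
near-line peaks are appropriate for the sweep experiments (they localize
power precisely within bands) but cannot be recovered by a fitter bounded
at 1 Hz. Recovery tests therefore use fit-compatible widths (≥ 1 Hz),
while sweeps use the tabulated values verbatim.

*Band assignment and parameterized ratios.* A fitted peak belongs to a
band when its center lies inside the band (inclusive); with several
candidates the highest-power peak wins, exact ties going to the lower
center frequency. A parameterized ratio divides the assigned peak powers
of two bands — periodic power with the aperiodic component already
removed — and is absent when either band lacks a peak; absent values are
excluded listwise downstream.

## Parameter sweeps

`single_param_sweep()` varies one parameter over its tabulated grid while
all others sit at their defaults (theta 6 Hz, alpha 10 Hz, beta 21.5 Hz,
each power 0.5 au, bandwidth 0.1 Hz; offset 0; exponent 1), simulating
one spectrum per grid point. `paired_param_sweep()` does the same over
the Cartesian product of two grids. With noise disabled the sweeps are
deterministic, and every 2-D grid's slice at a parameter's default equals
the corresponding 1-D sweep bit for bit — an identity the tests assert.

The bandwidth rows of the sweep table carry a default (0.1 Hz) outside
their own sweep range (0.2–0.4 Hz). The values are used exactly as
tabulated; we document the anomaly rather than "correcting" it, since the
census result does not depend on it.

`count_affected_params()` formalizes the headline census: a parameter
*alters* the ratio when the ratio's range across its sweep exceeds 1e−6
relative to baseline — far above accumulated float error (~1e−15) and far
below any genuine effect at the tabulated values. The ten parameters
counted are theta and beta {CF, PW, BW}, alpha {CF, PW}, offset, and
exponent: this is the only enumeration consistent with both the census
total (8 of 10) and the stated exceptions (offset and alpha power).
Alpha bandwidth does influence theta/beta — its tails cross the 8 Hz and
13 Hz edges once widths are non-negligible — and is available as an
eleventh sweep parameter, but it is bookkept outside the census.
The two exceptions are exact, not approximate: offset cancels
multiplicatively, and at the tabulated 0.1 Hz width the alpha peak's
tails underflow to zero more than two bins from 10 Hz, so alpha power
contributes nothing to either ratio band at working precision.

## Welch estimation and time-series synthesis

`welch_psd()` averages Hann-windowed modified periodograms (2-s windows,
25% overlap by default, giving 0.5 Hz resolution), scaled as a one-sided
spectral density and restricted to 1–35 Hz. Mean (not median) averaging
and the Hann window are conventional defaults. Segmentation is delegated
to `signal::specgram()`; the scaling satisfies a Parseval check (sum of
density × bin width ≈ signal variance) that the tests enforce.

`synth_time_series()` inverts the model: the target spectrum is evaluated
as a linear density at every positive Fourier frequency of the output
signal, each component gets amplitude $\sqrt{2\,S(f)\,\Delta f}$ and an
independent uniform phase, and the signal is the inverse FFT. The default
sampling rate is 500 Hz and the default duration 30 s — the usable length
of one eyes-closed resting block. With ~19 averaged segments the Welch
log-spectrum of a synthesized signal matches its target within about
0.06 au RMS, and round-trip exponent recovery (synthesize → Welch → fit)
lands within 0.1 of the target in ≥ 95% of seeds, which the acceptance
suite checks over 50 seeds.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a developmental
resting-state EEG study: 111 subjects, 111 channels, 5 eyes-closed
blocks; ages from a truncated normal on 6–44 years whose truncated
moments are matched to mean 15.79 and SD 8.03 (the underlying normal
parameters are solved numerically, so the generated sample really does
have the stated moments); an aperiodic exponent with a **negative** age
slope; and dominant, variable alpha power. The exponent–age sign
deserves a note: the emulation target's point estimate and interval
disagree in sign in the source material, and the interval's sign
(negative, i.e. spectra flatten with age) agrees with the developmental
literature, so the generator defaults to a negative slope; it is a config
field and can be set to anything.

The hierarchy is: subject-level draws (age, offset, exponent, per-band
peak presence and parameters) → a smooth cosine gradient over the ordered
channel index that multiplicatively modulates exponent and alpha power
(a stand-in for spatial topography; there is no electrode geometry) →
per-block jitter on every parameter → one simulated spectrum per cell,
with ground truth stored losslessly alongside.

Peak prevalences default to alpha 1.0, theta 0.6, beta 0.6. No detection
rates are reported for the emulation target; these values are declared
assumptions chosen so that parameterized ratios exhibit realistic
missingness (a parameterized theta/beta ratio exists only when both peaks
do). All distributional defaults for peak parameters are likewise
assumptions, surfaced in the config object and the run manifest.

**What passing tests do and do not show.** The generator reproduces the
statistical skeleton the analyses need — hierarchical variance,
prevalence-driven missingness, an age-linked exponent, alpha dominance, a
shared spatial gradient. It does not reproduce electrode geometry,
artifacts, line noise, non-Gaussian peak shapes, knees in the aperiodic
component, or the true joint distribution of peak parameters in human
EEG. Results on synthetic cohorts therefore validate the *pipeline and
its logic* (what the measures respond to, given known ground truth), not
any empirical claim about a particular dataset.

## Statistics

All correlations are Spearman (Pearson on average ranks; ties get
average ranks), with listwise deletion of missing pairs. Confidence
intervals are percentile bootstrap over paired resamples (default 5000
resamples, 95% level). Differences of correlations are tested by
computing the difference on each resample of the shared triples —
optionally on absolute values, comparing magnitudes while ignoring
direction — and reading a two-sided empirical p from the distribution:
$p = 2\min(\Pr[\Delta \le 0], \Pr[\Delta \ge 0])$, clipped to
$[2/(B+1), 1]$ so a finite number of resamples never reports $p = 0$.
Resamples that collapse to zero rank variance are skipped and counted.
Observation pairs are put in a canonical order after listwise deletion,
so bootstrap output is invariant to how the caller ordered the data; all
resampling is seeded. No multiple-testing correction is applied anywhere;
tables report raw p and CI only.

Subject-level analyses use channel averages by default; a `"pool"` mode
treating subject × channel rows as observations is provided because
"across all channels" analyses can reasonably mean either, and the two
modes are labeled in output.

## Problem sizes in the packaged experiments

The packaged experiments are sized for a laptop-class single core: the
cohort experiments use 111 subjects × 5 channels × 1 block with 1000
bootstrap resamples (the cross-subject analyses need subjects, not
channels, and 5 channels are enough to exercise channel averaging); the
recovery suite uses 200 spectra; the Welch round trip uses 50 seeds.
The generator and statistics scale to the full 111 × 111 × 5 design
(spectra simulation is vectorized and takes seconds; fitting 60k+ spectra
is the only expensive step).

Two experiment configurations recur in the tests, chosen to realize the
stated study conditions. The *exponent-dominated* cohort widens
between-subject exponent SD to 0.3 and keeps periodic SDs small, with no
periodic age effects, so that the only age-linked driver of theta/beta is
the aperiodic exponent; on it, theta/beta correlates with the fitted
exponent more strongly than with either band's fitted peak power
(bootstrap difference p < 0.05), the raw ratio tracks age, and the
parameterized ratio does not — the dissociation in property form. The
*alpha-dominated* cohort widens alpha power SD to 0.35 and flattens
everything else; on it, the strongest correlate of both alpha-inclusive
ratios is alpha power (negative for theta/alpha, positive for
alpha/beta).

## Numerical choices and degenerate inputs

* Frequency grids and sweep grids include both endpoints and are built by
  count.
* `power_spectrum()` refuses non-positive frequencies (log-frequency must
  exist), non-increasing axes, and non-positive linear power.
* Zero-variance inputs yield absent (`NA`) correlations, never errors;
  fewer than 3 complete pairs likewise.
* `bootstrap_ci` on perfectly monotone data returns the degenerate
  interval [1, 1].
* Fit non-convergence returns a flagged result carrying the guess-stage
  parameters.
* `with_seed_`-style seeding restores the caller's RNG state, so library
  calls never perturb user scripts; `run_pipeline()` derives per-stage
  sub-seeds from one global seed so stages can be rerun in isolation.

## Known limitations

* The aperiodic model is knee-free; spectra with a bend below ~35 Hz will
  fit with a compromise exponent.
* The fitter assumes peaks are Gaussian in log10 power and at least as
  wide as its lower width bound; the near-line peaks of the sweep tables
  are intentionally outside its regime.
* The cohort generator's spatial structure is a 1-D gradient, not a scalp.
* Parameterized ratios inherit the detection behavior of the fitter:
  prevalence estimates below ~0.5 per band leave few complete pairs and
  wide CIs.
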