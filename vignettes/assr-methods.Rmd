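---
title: "Quantifying 40 Hz auditory steady-state responses across EEG, OPM and SQUID"
author: "assr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 40 Hz auditory steady-state responses across EEG, OPM and SQUID}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assr)
```

## The problem

The auditory steady-state response (ASSR) is an oscillatory brain response
entrained to an amplitude-modulated tone; with a 40 Hz modulation rate it is
one of the most robust paradigms in auditory and clinical neuroscience. How
well the response can be measured depends heavily on the sensor technology:
scalp EEG suffers from volume conduction (spatial smearing), conventional
SQUID magnetometers sit several centimetres from the scalp in a rigid
helmet, and wearable optically pumped magnetometers (OPMs) measure the field
within millimetres of the scalp, which boosts signal amplitude by roughly a
factor 2--3 over SQUID.

This package implements a complete, reproducible quantification pipeline
for such three-way comparisons: a seeded synthetic-data generator standing
in for real recordings (rarely deposited publicly for studies of this kind),
the preprocessing chain, a canonical-correlation spatial filter,
spectral SNR and inter-trial phase-coherence (ITPC) statistics over
chronological trial counts, and repeated-measures inference.

## The measurement model behind the generator

`sim_config()` + `simulate_recording()` produce continuous multichannel
sessions with the paradigm's structure: 100 trials amplitude-modulated at
40 Hz plus 4 each at 20 and 60 Hz (task catch trials), 1 s stimulation, and
a uniformly jittered 1.3--1.7 s inter-trial interval, so onset-to-onset gaps
fall in 2.3--2.7 s. The 1000 Hz carrier is never synthesized -- only the
response at the modulation rate matters to any analysis band below 60 Hz.

Each trial's source waveform is a damped oscillatory onset transient
(default 9 Hz, decay 70 ms) plus a steady-state sinusoid at the modulation
frequency with a 100 ms onset ramp and a 50 ms exponential offset decay.
Phase is locked to stimulus onset up to a Gaussian jitter
(`phase_jitter_sd_rad`, default 0.2 rad) and single-trial amplitude varies
log-normally (`amplitude_jitter_sd`, default 0.2).

The forward model is schematic rather than anatomical: sensors live on a 2-D
head disk, and the auditory sources project as a bilateral dipolar field
over the temporal clusters (OPM/SQUID) or a broad, spatially smeared
fronto-central potential (EEG). Dual-axis OPM sensors contribute two
channels per site, the second axis seeing a different projection at reduced
gain (default 0.6). OPM evoked gains carry the proximity factor
`amplitude_factor_vs_squid` (default 2.5, the middle of the reported 2--3
range). We deliberately do not use a conductor head model: the pipeline's
claims concern signal processing and statistics, not source localization.

Noise has four components:

* white sensor noise whose one-sided amplitude spectral density is drawn
  per channel from the published per-modality ranges
  (EEG 0.4--2.5 uV/sqrt(Hz), OPM 15--30 fT/sqrt(Hz),
  SQUID 2--3 fT/sqrt(Hz));
* 1/f neural background (default exponent 1), referenced at 40 Hz
  (EEG 1.5 uV/sqrt(Hz), OPM 26, SQUID 20 fT/sqrt(Hz)), half shared across
  channels through smooth random spatial patterns and half
  channel-specific, with a +-30% smooth spatial variation of level;
* a 50 Hz mains sinusoid;
* artifacts: blinks (asymmetric lid-sweep template, ocular-weighted,
  default 18/min, about 120 uV at the EOG for EEG) and muscle bursts
  (110--140 Hz band-limited, 0.3 s, on 2--6 random channels at 8x the
  ongoing band RMS, default 1.5/min).

Evoked amplitudes (EEG 0.6 uV, OPM/SQUID 7 fT at the best sensor before the
OPM factor) were chosen so that the per-modality single-trial
signal-to-noise ratios sit in the regime reported for this paradigm: EEG lowest,
SQUID intermediate, OPM highest, with none of the modalities fully
saturating the SNR statistic at 80 trials (see "A ceiling built into the
SNR definition" below). Everything is a pure function of the config and its
seed; identical inputs give bit-identical recordings.

What the generator does *not* emulate: anatomical variability across
participants (participants differ only by seed), heartbeat artifacts,
sensor drift and cross-talk, head movement, and any nonstationarity of the
evoked response across a session. Passing tests on synthetic data therefore
demonstrate the pipeline's correctness and its qualitative behaviour under
the assumed signal model -- not performance guarantees on real recordings.

## Preprocessing

`run_preprocessing()` applies, in a fixed order: epoching of the 40 Hz
trials into [-1, +3) s windows (half-open, so exactly `4 * fs` samples);
muscle screening at the native rate; downsampling to 500 Hz (zero-phase
order-8 anti-alias low-pass, integer decimation preserving t = 0); average
re-referencing (EEG only, EOG excluded from the mean); a 49--51 Hz
zero-phase Butterworth notch; variance screening; removal of flagged trials
and channels; ICA ocular cleanup; and the final 5--60 Hz band-pass.

The muscle screen must precede downsampling because its 110--140 Hz
pseudo-dataset does not exist below a 280 Hz Nyquist; this is the only
physically possible order. All filters are 4th-order Butterworth designs
applied forward-reverse (zero phase). Band-passes are realized as a
high-pass/low-pass cascade, which is numerically robust for corners such as
0.5 Hz at a 500 Hz rate; note that forward-reverse filtering applies the
squared magnitude response, so a 40 Hz tone retains 96.2% power through the
5--60 Hz band (order-4 low-pass at 60 Hz), not 100%.

Screening replaces the manual and semi-automatic steps of typical workflows with
thresholded robust statistics, so that every decision is reproducible:

* *muscle*: per-trial RMS of the 110--140 Hz pseudo-dataset across
  channels; robust z-score (median/MAD) > 4;
* *variance/flat*: per-trial and per-channel variance of a 0.5--80 Hz
  pseudo-dataset; per-trial robust z > 4; channels are screened on the log
  scale (spatial gain variation makes raw channel variances heterogeneous
  by construction) with the same threshold, plus a relative floor
  (`1e-6` x median) for flat channels. EOG channels are exempt.
* *ICA*: the decomposition (fast fixed-point ICA, `ica::icafast`, 30
  components after PCA reduction, fitted on a 15k-sample subsample of the
  5--40 Hz pseudo-dataset) is standard; the package's contract is the
  selection rule. A component is ocular if its time course correlates with
  the EOG proxy (|r| > 0.7) -- evaluated below 8 Hz, where blink energy
  lives, because the 5--40 Hz fit band itself contains little of it -- or
  if its topography loads on ocular/frontal channels more than 4x as
  strongly as elsewhere. Magnetic modalities without an EOG channel use
  the frontal-channel mean as proxy.

Robust screens assume a clean majority: if most trials contain an artifact
(e.g., artifact rates far above the defaults on very short sessions), the
median/MAD reference is itself contaminated and flags become conservative.
Trial chronology (`kept_trial_ids`) is preserved through every stage, which
the chronological trial-count analysis depends on.

## The canonical-correlation spatial filter

`fit_cca_filter()` computes channel weights maximizing the covariance
between band-limited single trials and the band-limited trial average
(39--41 Hz, 0.25--1 s). The arrangement is: X = channels x (window samples
concatenated over trials) from single trials; Y = the time-locked average
repeated per trial; only the first canonical pair is used, and only the
X-side weight vector is kept. Both covariance matrices receive a ridge of
`1e-6` x mean channel variance, which handles the rank deficiency of
average-referenced EEG; the canonical correlation is solved by a symmetric
eigendecomposition of the whitened cross-covariance product. With one
channel the filter degenerates to that channel.

`apply_spatial_filter()` projects the *full* 5--60 Hz data (not only the
fit band) onto the weights, producing the virtual channel. Because
canonical weights have an arbitrary sign, `fix_polarity()` evaluates the
individual's trial-average virtual channel at the local extrema of a
grand-average template built *without* the spatial filter (plain mean over
participants and channels, 0--1 s window) and flips the sign if the
template minima average higher than the maxima. Extrema closer than one
40 Hz cycle (25 ms, less one sample of slack for peak-position
quantization) are merged keeping the larger magnitude. The operation is
idempotent, and negating every input channel leaves the corrected virtual
channel unchanged.

Channel subsets for the three-way comparison (`select_channel_subset()`):
OPM and SQUID use 5 sites above each ear -- SQUID gradiometers are matched
by position to the canonical 5-site OPM arcs, and both axes of a dual-axis
OPM site are kept -- while EEG uses the 10 electrodes with the highest
group-average 40 Hz response amplitude, which lands on the fronto-central
cluster where temporal dipoles project. The filter is fitted once on all
retained trials and then evaluated per trial-count bin; fitting per bin is
possible but not the default, since it would confound filter estimation
noise with the trial-count effect under study.

## Spectral statistics

`power_of_average()` averages the selected trials first and then computes a
sliding-taper power map: at frequency f the Hanning taper lasts 7 cycles
(7/f seconds, rounded to an odd sample count), on a 1--60 Hz x 0.25--1 s
grid (0.5 Hz / 50 ms steps). Frequencies whose 7-cycle window cannot fit in
the epoch -- below about 2 Hz -- are reported as `NA`, never imputed, as
are time points whose window spills past the epoch edge.

`snr_from_power()` forms `power(40 Hz) / mean(power(20--38 and 42--48 Hz))`
with both numerator and denominator averaged over the valid analysis time
points: the SNR of time-means, not the time-mean of SNRs. `itpc_map()`
uses a Gaussian (Morlet-family) wavelet of 7 cycles, `sigma_t = 7/(2 pi f)`
truncated at +-3 sigma, on a 1--60 Hz (0.1 Hz step) x -1..2 s (0.25 s step)
grid; ITPC(f, t) is the resultant length of the per-trial unit phase
vectors, so it lies in [0, 1], equals 1 for identical trials, and has
expectation `sqrt(pi)/(2 sqrt(n))` under uniformly random phase.
`itpc_ratio()` divides the 40 Hz ITPC by the mean over 20--30 Hz (the noise
band stays below the signal to avoid smearing signal into it; the printed
definition has no symmetric upper band and we implement it as printed),
averaged over the stimulation-phase grid points 0.25, 0.5, 0.75 and 1.0 s.

### A ceiling built into the SNR definition

A 7-cycle taper at 42 Hz lasts only 0.167 s, so its main lobe is wide:
a pure 40 Hz tone leaks 87% of its power into the 42 Hz bin, 84% into
38 Hz, and still 16% into 48 Hz. Averaged over the noise bands this caps
the SNR of a noiseless 40 Hz tone at about 4.7. The cap is a property of
the method's own frequency-smoothing choices, and it produces exactly the
saturation shape the trial-count curves show: modalities with high
single-trial SNR (OPM) approach the ceiling within a few tens of trials
while EEG keeps climbing to 80. Comparisons between modalities remain
meaningful because all three are measured with the identical statistic.

`trial_count_curve()` recomputes a metric from the first k retained trials
(always chronological, mirroring a real experiment stopped at k trials) for
k in {1, 10, 20, ..., 80}; ITPC bins start at 10 because ITPC is undefined
for one trial. `percent_increase()` defaults to normalizing by the
comparison (second) value -- the only reading consistent with reported
increases above 100% -- with the literal first-value normalization
available via `baseline = "mod1"`.

## Repeated-measures inference

`rm_anova_two_way()` implements the classical fully-within two-factor
decomposition, each effect tested against its own effect x subject
interaction. Per effect, sphericity is assessed with Mauchly's test on the
orthonormal contrast scores, and the Greenhouse-Geisser epsilon
`(sum lambda)^2 / ((k-1) sum lambda^2)` (eigenvalues of the double-centered
level covariance, clamped to [1/(k-1), 1]) multiplies both degrees of
freedom when Mauchly rejects at 0.05 -- or when the test is not computable
(fewer subjects than contrasts, as with 9 trial-count levels and 8
participants), where correcting is the conservative choice. Partial eta
squared is reported from its sum-of-squares definition and satisfies
`F df1 / (F df1 + df2)` exactly. Post hocs use Tukey's honest significant
difference via the studentized range, with the within-subject residual
mean square of the relevant effect as error term (applied reports rarely state
the error-term convention; for two levels this reduces exactly to the
paired t-test). `pairwise_contrast_anovas()` runs one 2 x bins ANOVA per
modality pair plus per-bin Tukey contrasts for significance markers.

Two properties of these tools are worth stating precisely because they are
often quoted loosely: the GG correction can only reduce significance when
F >= 1 (for F < 1 shrinking both dfs may lower the p-value), and the
epsilon estimator is biased low in finite samples (mean about 0.96 under
perfect sphericity with 50 subjects and 3 levels, converging to 1 with
n). The test suite asserts both behaviours as measured.

## The study pipeline

`run_study()` executes the whole chain per participant and modality under
deterministic per-participant seeds derived from one master seed. Two
passes are needed because two quantities are group-level by definition: the
EEG electrode subset uses the group-average 40 Hz topography, and the
polarity template uses the grand average over all participants and
channels. Pass one simulates, preprocesses and caches epochs (on disk, in
the session temp directory); pass two selects channels, fits and applies
the spatial filter, fixes polarity and computes the metric curves,
optionally for both the comparable subset and the whole-head array
(`wholehead = TRUE`, the basis of `compare_subset_vs_wholehead()`).

Participants with fewer than `min_retained_trials` (default 70, the
conventional rule for this paradigm) retained trials in any modality are excluded from group
curves; the group ANOVA additionally requires a complete bin grid, i.e. at
least `max(bins)` retained trials. Outputs (results.csv, group summary,
ANOVA JSON, rejection reports, manifest with config hash and all derived
seeds) are byte-identical across reruns of the same config.

## Numerical choices and degenerate inputs

* Window lengths are rounded to odd sample counts so every taper/wavelet
  has an exact center sample; maps are bit-reproducible.
* Zero-phase filtering uses steady-state initial conditions and
  odd-reflection padding (verified against an independent reference
  implementation to ~1e-9), in a compiled kernel that processes channel
  blocks; a symmetric pulse stays symmetric to ~1e-6 relative.
* The CCA ridge default (1e-6 relative) is small enough not to bias
  weights on well-conditioned data and large enough to handle the rank-1
  deficiency introduced by average referencing; all-zero data is rejected
  rather than regularized into silence.
* ITPC coefficients with exactly zero magnitude (possible only on
  all-zero data) are dropped from the resultant rather than dividing by
  zero; single-trial ITPC requests are errors, not NaNs.
* Robust z-scores fall back from MAD to SD when the MAD is zero.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run everything at a reduced
but structurally faithful scale, chosen to exercise every code path with
group sizes small enough for routine re-execution: synthetic studies of
6--8 participants (a full study of this kind analyzes ~21--23), all three
modalities simulated at 500 Hz (the muscle band needs only a 280 Hz
Nyquist; EEG is natively 500 Hz), the full 108-trial sessions where trial
counts matter, 12-trial sessions where only mechanics are under test, and
500-replicate null calibrations for the type-I error checks. Inside
`run_study()` the time-frequency maps are evaluated on restricted grids
that cover exactly the bands and time points the SNR and ITPC-ratio
consume (20--48 Hz at 0.5 Hz for power; 20--30 Hz at 0.5 Hz plus the 40 Hz
bin, 0.25--1 s, for ITPC); the standalone map functions default to the
full 1--60 Hz grids. Group-level
directions (modality ordering, growth over trial counts, whole-head vs
subset) are asserted on these scales; real group-level magnitudes
are not reproduced -- the
generator is a stand-in, not a digital twin.

## Known limitations

* The schematic forward model cannot address topographic questions
  (e.g., how many OPM sites are optimal, or helmet-position matching
  uncertainty across sensor systems).
* The ICA criterion targets ocular components only; heartbeat components
  are not simulated and not specifically detected.
* The SNR ceiling discussed above means absolute SNR values are not
  comparable across different taper conventions; only within-convention
  comparisons are meaningful.
* `resample_epochs()` supports integer decimation factors only (all rates
  in the paradigm are integer-related).
* Mauchly's chi-square p-value is the standard large-sample
  approximation; at very small n it is approximate (the implementation
  cross-checks against the reference implementation in the tests).
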