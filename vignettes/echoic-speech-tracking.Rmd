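---
title: "Models and methods: neural tracking of echoic speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: neural tracking of echoic speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echostream)
```

## The problem

A long-delay echo adds a lagged copy of a speech signal to itself:
$m(t) = A\,s(t) + s(t-\tau)$, with delays $\tau$ of 0.125 s or 0.25 s and a
direct-sound gain $A$ of 1 (a "0-dB echo", echo as strong as the direct
sound) or 0.5 (a "6-dB echo", echo twice as strong). Fourier components of
the envelope whose period is $2\tau/(2k-1)$ are antiphase between the two
copies, so a unit-gain echo *cancels* the envelope at the echo-related
frequencies $(2k-1)/2\tau$ — 4, 12, ... Hz for $\tau = 0.125$ s and 2, 6,
10, 14 Hz for $\tau = 0.25$ s. Those slow modulations carry much of speech
intelligibility, yet listeners understand echoic speech without difficulty.
The package implements the modeling chain used to ask how cortical activity
can still track the canceled modulations: echoic stimulus construction, a
phase-coherence spectrum with a shuffle null, a synaptic-depression plus
gain-control adaptation simulator, and a comparison of three
temporal-response-function (TRF) encoding models (mixture, streaming,
idealized), all exercised on a seeded synthetic-data generator so the whole
chain runs without any external recordings.

## Stimuli

`make_echoic()` forms $A\,s(t) + s(t-\tau(t))$ with delays realized as
exact integer sample shifts (a non-integer shift is an error rather than an
approximation, because the envelope-cancellation property is exact only for
exact shifts). Variable-delay stimuli redraw the delay uniformly in
[0.125 s, 0.25 s] at every pause longer than 500 ms, with the switch placed
at the pause midpoint and a short (50 ms) crossfade; since the envelope is
silent there, the splice is inaudible by construction. The mixture keeps
the echo tail, so it is longer than the input by the maximum delay;
downstream alignment truncates to the common support.

For a signal whose autocorrelation vanishes at the echo lag, the mixture's
power is $(A^2+1)$ times the direct power, i.e. RMS gains of
$10\log_{10} 2 = 3.01$ dB ($A = 1$) and $10\log_{10} 1.25 = 0.97$ dB
($A = 0.5$). These are the package's first sanity targets
(`rms_gain_db()`).

One-channel noise vocoding (`vocode_one_channel()`) replaces each stream's
fine structure with envelope-modulated Gaussian noise (Hilbert envelope
low-passed below 160 Hz, fourth-order Butterworth; carrier low-passed below
4 kHz), vocoding the direct sound and the echo separately before mixing and
matching the output RMS to the non-vocoded mixture. This removes the
spectro-temporal cues that support segregating the echo from the direct
sound while leaving the envelope intact.

`segment_pauses()` needs a silence threshold the source description does
not provide; it uses 5% of the median envelope over voiced frames, which is
invariant to overall gain.

## The synthetic-data generator

The generator stands in for the study conditions: narrated speech of
roughly 13 minutes per condition and 204-gradiometer recordings. It is a
first-class, tested module, not a fixture.

**Envelopes** (`speech_like_envelope()`): a two-state speech/pause
semi-Markov gate times syllable-like pulses. Speech stretches have
Gamma-distributed durations (shape 2.2, mean 3.4 s, truncated to
0.4–11.2 s, matching the printed pause statistics); pauses draw uniformly
from 0.55–1.1 s, so every pause qualifies as a delay-switch point.
Within speech, Hann-shaped syllables of 90–150 ms with lognormal amplitudes
follow Gamma inter-onset intervals (shape 5, mean 210 ms), yielding a
modulation spectrum peaked in the 2–8 Hz syllabic range. Envelopes are
generated at 200 Hz so both echo delays are whole samples, and decimated to
the 100 Hz analysis rate afterwards.

The voiced-part autocorrelation at the echo lags is near zero on average
across seeds (about $-0.03$ at 125 ms) but single 2-minute tracks can reach
about $-0.1$; making the syllable process more irregular would push the
modulation peak out of the 2–8 Hz band, so the mild residual correlation is
accepted and documented. The RMS-gain results do not depend on it: the
audio carrier (`synth_speech_audio()`) is envelope-modulated low-passed
white noise, which is serially uncorrelated, so the *waveform*
autocorrelation at the echo lags is zero in expectation.

**Recordings** (`synth_recording()`): per channel, response = mixing gain
$\times$ sum over predictor streams of (ground-truth kernel $\ast$ stream
envelope) + 1/f background + white sensor noise. The regimes define the
streams: `mixture` encodes the whole echoic envelope with one kernel,
`streaming` encodes direct and echo envelopes with distinct kernels,
`idealized` encodes the direct envelope only. Ground-truth kernels are
biphasic gamma shapes, 0.5 s long, peaking near 50 ms (direct) and 100 ms
(echo, higher amplitude). Mixing gains (random sign, magnitude 0.5–1.5)
belong to the *participant*: pooled conditions must share them
(`synth_participant()`), otherwise no single per-channel kernel can explain
the pooled data. SNR is defined per channel as the variance ratio of the
stimulus-driven signal to the total noise; the background is 80% 1/f and
20% white, matching the broadband character of sensor noise.

What the generator does **not** emulate: phonetic content, pitch and
prosody, realistic sensor topographies or forward models, eye/cardiac
artifacts, and inter-participant variability beyond seed-to-seed envelope
and gain differences. Passing tests therefore show that the analysis chain
recovers what it is designed to recover under these statistics — not that
it would behave identically on real recordings.

## Phase coherence

Envelope and response are cut into non-overlapping 2-s epochs (rectangular
window, plain DFT, 0.5-Hz bins; the trailing partial epoch is dropped).
With stimulus and response phases $\alpha_{ft}$, $\beta_{ft}$ and
$\theta_{ft} = \alpha_{ft} - \beta_{ft}$, the coherence at frequency $f$
over $T$ epochs is

$$C(f) = \frac{\left(\sum_t \cos\theta_{ft}\right)^2 +
\left(\sum_t \sin\theta_{ft}\right)^2}{T^2},$$

the *squared* length of the mean resultant: 1 for a constant phase lag, and
exactly $1/T$ in expectation for independent signals. The squared form is
the package default; `type = "resultant"` gives the unsquared mean
resultant length (chance $\approx 0.886/\sqrt{T}$) for comparison with the
inter-trial-coherence convention. The squared convention matters for the
ideal-tracking benchmark: an epoch-windowed DFT retains a boundary term of
relative size $\sqrt{\tau/2L}$ at the canceled bins (content in the first
and last $\tau$ of each $L$-second epoch has no cancellation partner inside
the window), so the *resultant* at a notch is of order 0.15–0.25 for any
realistic envelope, while its square stays below 0.07 — the regime in which
"ideal tracking of the mixture loses the direct envelope" is a meaningful
statement. Both the notch values and the $1/T$ chance level are verified
against Monte-Carlo oracles in the tests.

The chance level (`chance_null()`) randomly permutes the stimulus epochs
(identity permutation included), recomputes the coherence per shuffle,
averages observed and null values across channels (the group convention;
per-channel nulls are available), and reports one-sided
$p = (M+1)/(n_{\mathrm{shuffles}}+1)$ with Benjamini–Hochberg adjustment
across bins.

## The adaptation model

Per spectrogram channel $c$, with nonnegative input $s(t,c)$:

$$r(t,c) = \max(s(t,c) - D(t,c),\, 0)\; G(t,c),$$
$$D(t,c) = V\Big(1 + \sum_{n\ge 0} s(t-n,c)\, W(n)\Big),\qquad
G(t,c) = \frac{1}{1 + \sum_{n\ge 1} r(t-n,c)\, W(n)},$$

where $W$ is a raw (unnormalized) Hann window of width $\tau_{sd}$
(depression) or $\tau_{gc}$ (gain control) at the 200-Hz frame rate, and
$V \in (0,1)$ is the firing threshold. The gain-control sum starts at the
first *past* frame — including the current output would make $r(t)$ depend
on itself — while the depression sum keeps the current input. Because the
threshold is scale-dependent and no input normalization is prescribed,
spectrograms are normalized so their 95th percentile equals 1 before
adaptation (`normalize = TRUE`); when several pooled sessions feed one
TRF, `fit_adapted_trf()` normalizes them jointly so $V$ means the same
thing in every condition. The recursion is implemented in C++ with a
plain-R double loop kept as an independent oracle; the two agree bit for
bit.

Raw Hann weights make the depression strong for sustained inputs, so the
model behaves as an onset-emphasizing nonlinearity. On a 0-dB echoic
mixture it attenuates the echo's contribution and *restores* coherence with
the direct envelope at the echo-related frequencies; on a 6-dB echo
(echo twice the direct sound), attenuating the echo makes the two streams
more similar in amplitude and *deepens* the cancellation. This sign flip is
asserted in the acceptance tests at fixed mid-grid parameters
($V = 0.2$, $\tau_{sd} = \tau_{gc} = 300$ ms).

`fit_adaptation_params()` grid-searches $V$ (step 0.05) and the window
widths (50–450 ms, step 50 ms), maximizing the correlation between the
summed adapted response and the direct envelope averaged over sessions,
with ties broken toward the smallest parameters.

## TRF models

Three encoding hypotheses are compared on lagged designs with lags 1–100
samples (10 ms to 1 s at 100 Hz):

* **mixture**: $r(t) = \sum_\tau \mathrm{TRF}(\tau)\, s_m(t-\tau) + e(t)$
  with $s_m$ the echoic-mixture envelope;
* **streaming**: separate kernels for the direct and echo envelopes;
* **idealized**: the direct envelope only.

With a single fixed delay the echo envelope is the direct envelope shifted,
so the streaming design is rank-deficient (a warning reports the
singular-value diagnostic); conditions with different delays are pooled to
make it identifiable, with rows whose lag window would span a session
boundary dropped.

Kernels are ridge estimates with closed-form solutions, centering both
predictors and response (no intercept column). Predictive power is the
per-channel Pearson correlation between prediction and held-out response
under 10-fold cross-validation with **contiguous** folds (shuffled samples
would leak autocorrelated signal). The ridge strength is selected per outer
fold by nested cross-validation on the training folds only, from the grid
$10^{0..6}$ times the mean predictor column variance — tying the grid to
the column variance makes selection and predictive power invariant to
predictor rescaling, which is also what lets the identity limit of the
adapted TRF reduce exactly to the plain TRF. The fold machinery runs on
per-fold sufficient statistics ($X^\top X$, $X^\top Y$, sums and squared
sums), so the full grid costs little more than one pass over the data; a
naive per-fold refit is kept in the tests as an equivalence oracle.

`fit_adapted_trf()` passes each predictor stream through the adaptation
model (on a spectrogram synthesized from the stream's 200-Hz envelope)
before lag expansion and picks the adaptation parameters on the TRF-mode
grid ($V$ step 0.05, $\tau_{sd} < 800$ ms and $\tau_{gc} < 1400$ ms, step
200 ms) by cross-validated predictive power; the mixture model adapts the
mixture's own spectrogram. `bandlimited_trf()` band-passes responses and
predictors (zero-phase Butterworth) before the identical pipeline; note
that band-limiting the predictors makes the two streaming streams nearly
collinear again, which the rank diagnostic reports.

## Inference

* `exact_permutation_p()`: all $2^N$ sign flips of the per-participant
  condition differences are enumerated; with $M$ permuted means strictly
  above the observed one, $p = (M+1)/(2^N+1)$. Ties count as not exceeding,
  which is mildly anti-conservative at the margin; the achievable floor is
  $1/(2^N+1)$. Beyond $N = 20$ the function refuses unless an explicit
  Monte-Carlo sample size is given — the fallback is never silent.
* `bootstrap_unpaired_p()`: group A is resampled with replacement; with
  $M$ resampled means strictly below the comparison mean,
  $p = (M+1)/(n_{\mathrm{boot}}+1)$. This exceedance rule does not model
  the comparison value's own sampling noise: it is calibrated against a
  well-estimated reference (measured type-I $\approx 0.06$ at $n = 30$
  against the null mean) and anti-conservative when both groups are small
  (measured $\approx 0.12$ at $n = 15$ vs $12$) — the tests characterize
  both regimes. A jackknife-accelerated BCa interval
  (`bootstrap_bca_ci()`) is provided as a companion utility.
* `fdr_adjust()` wraps the Benjamini–Hochberg step-up adjustment
  (`stats::p.adjust`), validated against the hand-computed formula in the
  tests.

## Preprocessing and orchestration

`preprocess()` decimates recordings to 100 Hz (staged anti-alias
filtering) and applies a linear-phase FIR band-pass, 0.8–10 Hz, designed
from a 6-s Hamming window; the 3-s constant group delay is compensated by
dropping the first 3 s of filter output. With a transition width comparable
to the 0.8-Hz edge, the realized edge attenuation is $-3.7$ dB at 0.8 Hz
and $-9.1$ dB at 10 Hz rather than a nominal $-6$ dB; the passband
(1.5–9 Hz) is flat to within 0.1 dB and 0.1-Hz drift is attenuated by more
than 80 dB, which is what the analyses rely on.

`run_experiment()` reproduces the three study designs end to end on
synthetic participants — coherence at the echo-related frequencies with its
shuffle chance level, the pooled-delay TRF comparison, and the permutation
contrasts with FDR — deterministically from one master seed.

## Numerical choices and problem sizes

* Envelopes are generated at 200 Hz (both delays integer shifts) and
  analyzed at 100 Hz; decimation is staged in factors of at most 8 because
  transfer-function Butterworth filters are unstable at very small
  normalized cutoffs.
* Filters can undershoot; envelope tracks are clipped at zero afterwards.
* Ridge fits guard against degenerate (constant) predictions by reporting
  zero correlation instead of NaN.
* Test and example problem sizes are chosen for quick desk-scale runs: the
  RMS-gain checks use 120–300 s of audio; the ideal-tracking benchmark uses
  ten 13-minute envelopes; TRF model-selection recovery uses 12 simulated
  participants with 204 channels at $-10$ dB SNR and two pooled 2-minute
  conditions each; the remaining unit tests run on seconds-long fixtures.

## Known limitations

* The 128-band front end (`auditory_spectrogram()`) is an FFT-masked
  log-spaced filterbank with analytic-signal envelopes — a stand-in with
  the same interface as a cochlear model (128 narrowband envelopes at
  200 Hz), without compression or lateral inhibition.
* The modulation spectrum uses one full-length DFT per band (no windowed
  averaging), favoring frequency resolution over variance.
* The synthetic vocoded-speech analog makes band envelopes combine
  incoherently, so the 6-dB echo's modulation notch is shallower than with
  a fine-structured carrier; tests assert its attenuation relative to the
  0-dB notch rather than an absolute depth.
* The exceedance bootstrap's small-group anti-conservatism is a property of
  the procedure itself, preserved deliberately; use the BCa interval when
  calibrated uncertainty on a single group mean is needed.
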