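---
title: "Methods: from pressure and fluorescence traces to chemosensory response classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pressure and fluorescence traces to chemosensory response classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnotrace)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage computes, which tunables matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The experimental setting

An unrestrained mouse breathes in a plethysmography chamber while a
head-mounted miniscope images GCaMP6 fluorescence from a brainstem nucleus
at 10–20 frames/s. Gas steps through hypercapnic epochs — typically 3 min
each of 0, 3, 6 and back to 0% inspired CO₂ for the RTN and raphe, or
0/6/9/0% for the lateral parafacial region — while a gas analyzer reads the
chamber inflow through a delay line of roughly 15–20 s. The pipeline starts
downstream of movie processing: its inputs are per-ROI fluorescence traces,
the calibrated pressure trace, and the recorded gas protocol.

## Plethysmography

Each breath is an inspiratory peak followed by an expiratory trough. The
segmenter lightly smooths the trace (20 ms), centres it with a 2-s running
median, and extracts alternating extrema pruned by a *local* prominence
floor: 20% of the rolling 10-s 10th–90th percentile range. A local floor is
essential because tidal volume roughly doubles across the protocol while
sniff breaths halve it; a single global threshold either drops sniff
breaths or admits noise. Tidal volume is peak minus trough, calibrated to
mL and normalized to body mass (default per gram — the normalization basis
is configurable); fR is breaths/min; minute ventilation is *defined* as
the product V_E = V_T × fR at every grid point, so the identity holds
exactly by construction. Times are seconds from recording start and all
intervals are half-open `[start, end)`.

Three event detectors sit on top:

* **Sniff bouts** — fR above `factor` (default 2) times the running
  60-s eupneic median for at least 0.5 s. The running median tracks the
  CO₂-driven baseline, so protocol steps (≤ 2× with the default
  multipliers) do not trigger it. Bout onsets are refined to the first
  supra-threshold breath.
* **Active expiration** — expiratory recruitment deepens the trough. The
  statistic is the scale-free trough-depth-to-peak-height ratio of each
  breath (tidal volume growth with CO₂ cancels), as a robust z against the
  baseline-epoch distribution, with the scale floored at a quarter of the
  median ratio so extrema measurement noise cannot pass for recruitment. A
  breath must also deepen its trough relative to the local (±31 breaths)
  median depth, and breaths inside (padded) movement bouts are excluded —
  segmentation is meaningless inside an artefact.
* **Movement** — broadband power (20–80 Hz, above any breathing harmonic
  content) on a 0.25-s short-time spectrogram. Bouts must exceed a robust
  z of 4 *and* sit 1.5 decades above the quiet floor for at least 0.3 s:
  vigorous sniffing leaves waveform harmonics in the band that clear a
  purely relative threshold but are orders of magnitude weaker than true
  movement. The detector is channel-agnostic so WBP-derived and external
  movement sonograms can be cross-validated.

## Calcium conditioning

F₀ is the 10th percentile of raw fluorescence over the baseline epoch —
robust to transients riding on it — and dF/F = F/F₀, which is invariant
under multiplicative gain. Transients are runs where the (3-frame
smoothed) trace exceeds 3 robust SD above a 30-s running median; the noise
scale comes from frame-to-frame differences so sparse transients do not
inflate it. Because every genuine transient has a fast rise, a
supra-threshold excursion is split wherever a further rapid-rise burst
(slope above 3.5 robust SD of the frame-to-frame slope) lifts the signal
by twice the detection threshold; events so close that their rises fuse
remain merged, a documented resolution limit.

Decay kinetics are fitted as a single exponential starting four rise-times
past the peak — by then the residual rise component, which falls on its
own much faster time scale, is a few permille of the decay and cannot bias
τ — down to 5% of amplitude, on a 3-frame boxcar of the trace (a centred
boxcar of an exponential is a rescaled exponential with the same τ). The
offset term is bounded to a few percent of F₀, the physical scale of
baseline error; leaving it free lets it trade against τ on short windows
and roughly doubles the estimator spread. On noise-free kernels the fitted
τ is within 1% of truth; at default noise the median per-event error on
well-isolated events is ≈ 7–8%.

The four QC criteria are operationalized as: (1) an upstream morphology
flag carried on the trace (cell features are judged on the movie, not the
trace); (2) movement independence — fails only when at least half the
transient onsets fall inside (padded) movement bouts *and* a one-sided
Fisher test on the 1-s-bin bout-by-transient contingency is significant at
α = 0.01; (3) at least one detected transient; (4) the linear trend of the
lower dF/F envelope (10th percentile per 30-s block) below 5% of F₀ per
minute, a proxy for a constant focal plane. Every statistic is computed on
dF/F, so verdicts are gain-invariant.

Background (null-signal) subtraction fits a least-squares scale between a
cell's dF/F and a fluorescence-free landmark ROI over non-event frames and
subtracts; a shared additive artefact cancels exactly in the noise-free
case.

## Epoch statistics and their two nulls

Statistics are computed on delay-corrected epochs (interior protocol
boundaries shifted earlier by the analyzer delay, default 17.5 s) with
movement-bout frames excluded. Two different null models answer two
different questions, and conflating them was the single largest source of
error during development:

* The **epoch deltas** Δ_lo and Δ_hi (mean dF/F in each hypercapnic epoch
  minus baseline) are tested with a Welch t on 20-s sub-block means. This
  asks whether two epochs differ beyond the within-epoch variability of
  the trace. A circular-shift null is the wrong tool here: for a strongly
  modulated neuron the shift relocates the response itself into the null
  and destroys power exactly where it matters, while for an unstructured
  trace it is anticonservative.
* The **onset-window elevation** (first 60 s of hypercapnia versus
  baseline) *is* tested against the circular-shift null over all
  admissible shifts (≥ 30 s from alignment). For a window much shorter
  than the record this asks precisely the right question — could an
  excursion this large arise at a random alignment — and it resolves
  p ≈ 10⁻⁴ deterministically.

The derived quantities are the onset-window peak (maximum 10-s rolling
mean elevation), the late-hypercapnia activity (last 60 s of the final
hypercapnic epoch), the adaptation index `1 − late/peak`, the
recovery-epoch activity, and per-epoch transient rates.

## The two-component analysis

Each neuron is a point at (Δ_lo, Δ_hi). Adapting cells respond more to the
first step than the second and fall below the identity line; graded cells
above it; inhibited cells in the negative quadrant; non-responders near
the origin. Region assignment is significance-first: a neuron is
near-origin unless it is responsive at all (either delta significant at
α = 0.01, or the onset excursion significant at α = 0.05). A purely
geometric near-origin radius — for example half the population robust SD
of the deltas — misplaces low-rate cells whose epoch means wander by
counting statistics alone; the significance rule keeps ≈ 98% of generated
non-coders at the origin. The geometric radius remains as a fallback for
bare coordinate input.

## The classification cascade

Rules are evaluated in priority order; behavioural-event classes outrank
CO₂ classes because their evidence is time-locked and specific, and each
CO₂ rule is stricter than those after it.

1. **Exp** then 2. **Sn** — event-locked evidence from `onset_latency()`
   against detected expirations / sniff bouts: at least 5 matched events,
   ≥ 70% of events matched, median lead within [0.05, 1.2] s, ≥ 80% of
   leads positive, lead IQR ≤ 0.35 s, and a one-sided sign test at
   α = 0.05. The IQR condition carries most of the specificity: genuinely
   locked activity has a tight lead distribution, while chance matches on
   a busy trace scatter across the ±2-s window.
3. **I** — baseline transient rate ≥ 0.08 events/s ("spontaneously active
   at rest") with both hypercapnic rates below half of it ("greatly
   reduced"). Offset rebound is typical but not required.
4. **E_A** — significant onset excursion whose peak towers at least 10
   baseline robust SDs (these cells are near-silent at rest, so a real
   onset burst is enormous on that scale), onset-window transient rate
   ≥ 0.1 events/s (a burst, not one lucky event), adaptation index > 0.5,
   Δ_lo > 0, and below-identity placement. Rebound after offset supports
   but is not required.
5. **E_G** — Δ_hi > Δ_lo > 0, both block-significant at α = 0.05,
   above-identity placement, and recovery below half of Δ_hi ("returned
   to baseline").
6. **T** — active in every epoch (rate ≥ 0.06 events/s), no significant
   epoch modulation, and *no* significant breathing-frequency
   correlation. The last condition is a deliberate refinement: without
   it, respiratory-related cells — active in all epochs with flat epoch
   means by construction — are absorbed by the tonic rule before their
   own rule is ever reached.
7. **NC-RR** — significant fR correlation (α = 0.01) without CO₂
   modulation and at least 25 transients (a correlation needs events to
   carry it).
8. **NC** otherwise. Neurons with an epoch lost to movement are
   `unclassifiable` and excluded from composition counts.

The fR correlation resamples dF/F and fR to 2 Hz, removes a per-epoch
linear trend from both (isolating breath-to-breath variability from the
stepped CO₂ response), smooths both over 5 s, scans lags within ±5 s, and
takes significance from the maximum-|r| statistic over *all* admissible
circular shifts of the calcium series — a deterministic superset of a
seeded 1000-shift permutation that preserves autocorrelation. Ventilation
samples inside movement bouts are bridged by interpolation, and sniff
bouts are bridged too for this particular correlation: sniffing is a
separate behaviour with its own class, and its fR spikes only dilute the
eupneic-variability signal the rule is after.

One caveat this machinery makes explicit: a correlation across a *single*
gas transition has an effective sample size near one, and the shift null
correctly refuses to certify it on a per-neuron basis. Claims about
activity tracking ventilation through a transition are therefore tested at
the population level (sign consistency across neurons), not per cell.

## Event-triggered analysis

Triggered averages align dF/F segments to event onsets, subtract each
segment's value at the left window edge, and average; clipped events are
dropped and counted. Onset latency matches each behavioural event to the
nearest calcium onset within ±2 s; the lead is `event onset − Ca onset`,
positive when calcium precedes (the sign convention throughout). Calcium
onsets are the last sub-threshold frame before the 3-robust-SD crossing,
the same rule the transient detector uses. Histograms use 0.1-s bins,
which resolve 0.3–0.8-s leads at 10–20 frames/s; per-CO₂-level summaries
are emitted when a protocol is supplied, and both per-event and per-neuron
summaries are available since published lead ranges do not always say
which aggregation they used. The estimator's bias at default noise is
under 0.05 s for true leads in [0.2, 1.0] s — onset quantization (one
frame) and the smoothing window nearly cancel.

## The synthetic-data generator

The generator's role is to emulate the statistical structure the analysis
assumes, with ground truth for every quantity a detector estimates.

**Breathing** is built breath by breath: one asymmetric sinusoid cycle per
breath (inspiration 35% of the cycle; the trough a fixed fraction,
default 0.25, of the peak), amplitude encoding V_T — the simplest shape
satisfying the peak-minus-trough definition. fR and V_T follow the CO₂
protocol with sustained multipliers (defaults 1/1.35/1.7/2.0 and
1/1.5/2.0/2.4 for 0/3/6/9%), a 15% overshoot at each step relaxing with
τ = 30 s (so V_E rises at each step and partially adapts, as real
plethysmography does), a slow smooth fR wander (SD 8%, 6-s correlation
scale, high-passed so 60-s means stay centred — it models breath-to-breath
variability, not drift), and per-breath jitter. Sniff bouts (default
1/min, 2 s, 3× fR capped at a 12-Hz physiological ceiling, 0.5× V_T),
active expirations (0.4/min per %CO₂ during hypercapnia, 5× trough
depth), and movement bouts (0.5/min, 2 s, broadband at 6× the baseline
amplitude, always contaminating the WBP channel and never the calcium
channel unless a defect is injected — fluorescence controls show movement
alone yields only small fluctuations) are injected at known times. The
analyzer delay is a pure shift of the recorded protocol boundaries,
default 17.5 s.

**Calcium** events are drawn from an inhomogeneous Poisson process (no
firing statistics being established, Poisson is the minimal assumption)
shaped per class: adapting cells burst at the first CO₂ step (peak
0.8 events/s, τ = 20 s) with an offset rebound; graded cells scale with
the level (0.08 events/s per %CO₂); inhibited cells drop from
0.3 events/s to a tenth of that; tonic 0.15 events/s flat; non-coders
sporadic at 0.02 events/s; respiratory-related cells follow the rectified
standardized fR wander with gain 2.5 at base 0.15 events/s. Sniff- and
expiration-locked cells place one event a configurable lead ahead of each
behavioural event (sniff leads uniform in 0.4–0.8 s; expiratory leads per
CO₂ level, defaults 0.5 s at 6% and 0.3 s at 9%). Events convolve with a
peak-normalized difference-of-exponentials kernel (rise τ 0.2 s; decay
1.5 s for the slow indicator, 0.7 s for the fast one — the two indicator
variants differ in kinetics, not mechanics), ride on dF/F noise of
SD 0.05 and a slow 2% optical drift, and scale by lognormal amplitudes
(mean 1.0, CV 0.2). QC-defect traces (absent morphology, movement-locked
events, flat, 10%/min focal drift) can be appended for testing the
exclusion accounting.

Where the literature states a value (epoch structure, analyzer delay,
sniff and expiratory lead ranges, frame-rate band), the defaults are those
values; where it does not (sniff fR, expiration magnitude, event rates,
noise), the defaults are fixed at what a respiratory physiologist would
call typical for an adult mouse at thermoneutrality, and are configurable.
What the generator does **not** emulate: optics (no pixel-level movies, no
GRIN-lens vignetting), indicator nonlinearity and saturation, breathing
waveform detail beyond the two-segment sinusoid (no end-expiratory pause),
non-stationary arousal states, or correlated noise across ROIs. Passing
tests therefore demonstrate that the pipeline recovers the structure it
assumes, at realistic signal-to-noise — not that it is robust to every
pathology of real recordings.

## Numerical choices and degenerate inputs

Time grids are uniform; trace containers carry the rate and start time.
Flat pressure traces yield empty breath tables, not errors; a constant
series makes a correlation undefined and is flagged; an expiration
threshold of zero degenerately flags every breath, and a sniff threshold
of zero one record-spanning bout. Deterministic tie-breaks: equal-depth
extrema prune left-to-right; the taller peak survives a sub-cycle merge.
Per-neuron seeds derive from the master seed by a fixed affine map modulo
a 31-bit prime, so populations are reproducible neuron by neuron and a
fixed configuration is byte-identical. All circular-shift nulls enumerate
every admissible shift rather than sampling, making p-values
deterministic.

Problem sizes used in the shipped tests — 12-minute recordings, 98-neuron
populations, five-neuron latency cohorts with ≥ 50 events per CO₂ level —
mirror the study scale; the full suite and the acceptance script each run
in a few minutes on one CPU.

## Known limitations

* Transients whose rises fuse (closer than ≈ 0.3 s) are one detection;
  event-rate estimates under-count at sustained rates above
  ~0.3 events/s. Rules that consume rates use ratios or generous margins.
* The raphe/RTN accounting of "CO₂-modulated" is ambiguous when
  sniff-coding cells are counted; `classify_population()` reports both
  the strict (E_A+E_G+I) and the sniff-inclusive number rather than
  choosing.
* QC criterion 1 is a pass-through flag; the package cannot judge
  morphology from a trace.
* The classifier's thresholds are calibrated for the default generator
  noise regime; real recordings with much lower SNR will need the
  `classify_config()` dials re-examined, which is why every qualitative
  phrase in the class definitions is pinned to one named, documented
  number there.
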