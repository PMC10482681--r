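---
title: "Behavioural states, photometry and metabolic coupling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural states, photometry and metabolic coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldstate)
```

# The analysis problem

Mice moved from thermoneutral housing into the cold face a trade-off:
staying immobile conserves heat, but elevated thermogenesis eventually has
to be paid for by eating. `coldstate` implements the computational side of
studying that trade-off: it segments second-by-second behavioural
annotations into a small number of latent states with a hidden Markov
model, summarises how animals move between those states, aligns
fibre-photometry calcium signals to state transitions, and detects — from
indirect calorimetry — the time at which food intake becomes coupled to
energy expenditure (the onset of cold-induced energy compensation, CIEC).

Because the raw recordings behind such experiments are rarely public, the
package ships seeded generators for every input it consumes. Each
generator exports its ground truth, so every stage of the pipeline can be
validated by recovery rather than by eyeballing.

# The behavioural state model

## Data model

An *ethogram* is a sequence of behaviour labels, one per 1-s bin, drawn
from a fixed 15-action vocabulary (sitting, shivering, head grooming,
turning, lower body grooming, moving out, eating, moving back, pushing
bedding, standing up, bedding retrieval, drinking, digging, grooming
tail, walking). The vocabulary order is frozen so that integer codes are
stable across runs: `sitting` is always code 0 and `walking` code 14.
Each bin holds exactly one label; files with overlapping annotations are
rejected rather than resolved, because the annotation protocol we target
records a single dominant behaviour per second. Simultaneous behaviours
(shivering while sitting, say) must be collapsed by the annotator — a
known divergence from what animals actually do.

## The categorical HMM

Behaviour labels $y_1,\dots,y_T$ are modelled as emissions of a hidden
state chain $s_1,\dots,s_T$ with $K=3$ states:

$$P(s_1 = i) = \pi_i, \qquad
  P(s_{t+1} = j \mid s_t = i) = A_{ij}, \qquad
  P(y_t = v \mid s_t = i) = B_{iv}.$$

The three states carry fixed semantic meaning: state 1 is energy
conservation (mass on sitting/shivering), state 2 exploration with
feeding (highest eating probability), state 3 exploration without
feeding.

Fitting is by Baum–Welch (EM). The implementation uses the scaled
forward–backward recursions (compiled, since the sequences are 10,800
steps long and the inner loops are unvectorisable); scaling is
numerically equivalent to log-space recursion and avoids underflow that
linear-space recursions hit within a few dozen steps. Decoding is by
Viterbi in log space with ties broken toward the lowest state index at
every backtrack step, so decoded paths are reproducible bit for bit.

Choices a user should know about:

* **Initialisation.** `init_params()` starts from a uniform transition
  matrix (equal probabilities for all transitions — the no-prior-information
  choice), uniform $\pi$, and an emission template that seeds each state
  with its expected behaviour family
  (`default_emission_template()`), with a 0.01 floor elsewhere. The
  template only breaks the label-permutation symmetry; recovery is robust
  to its details, and a multiplicative jitter (`jitter`, `seed`) is
  available for multi-start fits.
* **Multi-sequence pooling.** One model is fitted jointly to all animals:
  expected counts are summed across sequences, and each sequence restarts
  from $\pi$. Per-animal fits are just `baum_welch_fit()` on a
  single-element list.
* **$\pi$ re-estimation.** $\pi$ is re-estimated each iteration as the
  average first-step posterior across sequences. With three sequences it
  is weakly identified, which is fine: all downstream quantities depend
  on $A$, $B$ and the decoded paths.
* **Emission floor.** After every M-step, emission entries below $10^{-8}$
  are floored and rows renormalised. Behaviours unseen in one state would
  otherwise freeze at exact zero and could make later observations
  impossible under the fitted model.
* **Convergence.** Relative log-likelihood improvement below `tol = 1e-6`
  or `max_iter = 500`. The likelihood trace is retained in the fit object
  and is non-decreasing up to $10^{-8}$ slack — a property the test suite
  checks on a hundred random instances.
* **Label switching.** `assign_semantic_labels()` maps fitted states to
  the semantic 1/2/3 by: highest eating emission → state 2; of the
  remaining two, higher sitting + shivering emission → state 1; remainder
  → state 3. Ties go to the lower raw index.

## State summaries

`occupancy_fractions()`, `transition_counts()`, `bout_table()` and
`state_transition_events()` are straight counting on the decoded
sequence. Two conventions matter:

* A transition event is stamped at the **first bin of the new state**, so
  a peri-event window centred at 0 splits into pre-transition and
  post-entry halves.
* Transitions are counted on raw 1-s changes with no smoothing or minimum
  bout duration. A minimum-bout filter was considered and left out: it
  adds a parameter the annotation protocol gives no value for, and the
  HMM's diagonal-heavy transitions already suppress single-bin flicker.

# Photometry

The 470-nm channel carries the calcium-dependent signal; the 410-nm
channel is a calcium-independent reference sharing the motion and
photobleaching components. `fit_reference()` regresses the signal channel
on the reference over the **whole recording** (bleaching is a
recording-scale trend, so a per-event fit would confound it with the
response), and

$$\mathrm{d}F/F_t = \frac{F^{470}_t - \hat F_t}{\hat F_t},
  \qquad \hat F_t = a\,F^{410}_t + b.$$

The regression convention is a documented choice, not a reproduction of
any particular acquisition stack: sliding-percentile baselines are the
main alternative, and the regression was chosen because it uses the
information the reference channel exists to provide. One consequence
worth knowing: a large transient contributes its own few samples to the
fit, biasing the baseline by a fraction of a percent — negligible at
physiological transient rates, visible in torture fixtures.

Peri-event analysis aligns dF/F segments by nearest sample (event times
come from 1-s behaviour bins, so sub-sample interpolation would be false
precision). Events whose window does not fit inside the recording are
dropped and counted. Defaults follow the two event families: feeding
onsets use a $(-20, +10)$ s window, state-transition events $(-10, +10)$ s.
AUC is the trapezoidal integral in dF/F·s; peak is the signed maximum
times 100 (an inhibitory response reports a negative peak rather than
zero).

# Calorimetry and CIEC onset

Energy expenditure uses the abbreviated Weir equation,
$\mathrm{EE}\,(\mathrm{kcal/h}) = 60\,(3.941\,\dot V_{O_2} +
1.106\,\dot V_{CO_2})/1000$ with flows in ml/min. The coefficients are
the standard abbreviated-Weir constants (kcal per litre of gas) and are
arguments, not magic numbers. Hourly summaries average per-sample EE
within each hour relative to cold onset (hour 0 = start of the 3-h
temperature ramp) and difference cumulative intake across the hour
boundaries, converting grams to kcal at 3.56 kcal/g (the standard chow
density; 20 mg is the pellet quantum for dispenser-based intake).

The coupling statistic is a **sliding-window Pearson correlation over
pooled animal-hours**: at window centre $h$, all (animal, hour) pairs
with hour in $[h-1, h+1]$ contribute. This is a convention — the
underlying studies do not specify per-animal vs pooled, window length or
correlation type — and it is validated by recovery on synthetic data, not
claimed as a reproduction. Windows with fewer than 3 pairs or zero
variance are undefined (`NA`), skipped by the detector.

CIEC onset is the earliest window centre whose correlation reaches the
threshold (default $r \ge 0.5$) **and stays at or above it for every
later defined window** — the "remaining elevated thereafter" rule. A dip
below threshold pushes the onset past the dip; raising the threshold can
only delay the onset (a monotonicity the tests check). No sustained
window is a valid, reported outcome, not an error.

# What the generators emulate — and what they do not

* `simulate_ethogram()` draws states from a diagonal-heavy chain
  (self-transition ≈ 0.95, giving bouts of tens of seconds) and labels
  from well-separated emission rows; defaults are 3 animals × 10,800 s,
  the 180-min recording length at 1-s bins.
* `simulate_photometry()` builds both channels from a shared exponential
  bleach (τ = 3000 s) and a shared 2% sinusoidal motion artifact, adds
  channel noise, and injects double-exponential transients
  ($a(e^{-t/\tau_d} - e^{-t/\tau_r})$, defaults $a = 0.05$ dF/F,
  $\tau_r = 0.5$ s, $\tau_d = 2$ s, 20 Hz) into the 470-nm channel only,
  multiplicatively — so reference correction is actually exercised.
* `simulate_calorimetry()` ramps EE up by a factor of 2 over the 3-h
  23→4 °C transition, gives each animal-hour a shared lognormal
  fluctuation (sd 0.2), and emits 20-mg pellets as a Poisson process:
  constant 3 pellets/h before the programmed coupling onset (default 5 h
  post cold onset), rate proportional to excess EE after it. The gain
  (25 pellets per excess kcal/h) was set analytically so that Poisson
  counting noise and hourly EE variability combine to a post-onset pooled
  correlation near 0.8; defaults use 24 animals and 4 h baseline + 16 h
  post-onset at 1-min sampling. Basal VO₂ is 1.7 ml/min at RER 0.85 —
  ordinary resting values for a laboratory mouse.
* `simulate_rtpp()` alternates exponential chamber dwells whose means are
  in the target preference ratio, with a reflected random walk inside the
  occupied chamber of the standard 60 × 25 cm two-chamber box.

All generators are pure functions of their configuration and seed, and
leave the caller's RNG stream untouched.

These generators target the *statistical structure the pipeline assumes*,
nothing more. Real ethograms have annotator noise, behaviour-dependent
bout-length distributions and non-stationary emissions; real photometry
has hemodynamic contamination and non-sinusoidal motion; real calorimetry
has circadian structure the generator omits. Passing recovery tests
therefore demonstrates that the *analysis* is correct under its own
model, not that the model captures every property of real recordings.

# Validation scale and numerical choices

The test suite validates the HMM against exhaustive path enumeration on
200 random models (K ≤ 3, V ≤ 4, T ≤ 8), EM monotonicity on 100
instances, and full-scale recovery on 10 seeds of 3 × 10,800-bin
ethograms (fitted transition matrix within 0.05 of truth, decoding
accuracy ≥ 90% after semantic alignment). Calorimetry-onset recovery runs
20 seeds of the 24-animal default; photometry event-type separation runs
10 seeds. These sizes make the suite complete in well under a minute per
module while keeping every check at the data scale the defaults describe.

Degenerate inputs are handled deliberately: an observation impossible
under every state yields `-Inf` likelihood (not an exception), but
Viterbi refuses to decode such a sequence and names the first impossible
step; a constant reference channel is an error that points at the
mean-ratio alternative rather than silently producing a rank-deficient
fit; an all-identical ethogram is legal and converges to point-mass
emissions.

# Known limitations

* The three-state architecture is fixed by design; no model selection
  over K is offered.
* Emissions are categorical and time-homogeneous; no autoregressive or
  duration-explicit (semi-Markov) variants.
* Group-level hypothesis testing is out of scope: the package exports
  per-animal tables for external statistics.
* The sliding-window coupling statistic detects the onset of sustained
  correlation; it is not a causal or lagged-coupling analysis.
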