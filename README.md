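# coldstate

Analysis toolkit for cold-induced energy compensation (CIEC) experiments
in mice: behavioural-state segmentation, event-aligned fibre photometry,
and calorimetry-based detection of energy-expenditure/food-intake
coupling.

## The problem

A mouse moved from thermoneutrality into the cold must balance two
competing demands: staying immobile conserves heat, while elevated
thermogenesis eventually forces it to seek food. Experiments probing this
trade-off produce four kinds of time series — second-by-second behaviour
annotations (ethograms), two-channel fibre-photometry recordings,
indirect-calorimetry traces, and arena trajectories — and `coldstate`
implements the analyses that connect them:

1. **Behavioural states.** Ethograms over a fixed 15-action vocabulary
   are modelled with a 3-state categorical hidden Markov model
   $(\pi, A, B)$: state 1 = energy conservation (sitting/shivering),
   state 2 = exploration with feeding, state 3 = exploration without
   feeding. Fitting is multi-sequence Baum–Welch with scaled
   forward–backward recursions (compiled); decoding is Viterbi with
   deterministic tie-breaking; fitted states are mapped to their semantic
   identities by their emission profiles.
2. **State metrics.** Occupancy fractions, bout tables, transition
   counts (notably outbound transitions from the energy-conservation
   state) and the timestamps of specific state entries.
3. **Photometry.** dF/F via least-squares fit of the 410-nm reference to
   the 470-nm signal, peri-event extraction on a shared grid, trapezoidal
   AUC (dF/F·s) and peak dF/F (%) over configurable windows
   (feeding: −20…+10 s; state transitions: −10…+10 s).
4. **Calorimetry.** Energy expenditure from the abbreviated Weir
   equation, EE (kcal/h) = 60·(3.941·V̇O₂ + 1.106·V̇CO₂)/1000; hourly
   binning relative to cold onset; sliding-window Pearson correlation
   between pooled hourly EE and intake; and CIEC-onset detection as the
   earliest hour at which that correlation reaches threshold and stays
   there.
5. **Arena assays.** Real-time place-preference time fractions and
   preference change, and open-field centre-zone time/distance (centre =
   the concentric square holding 40% of the arena area).

Every input kind has a seeded synthetic generator with exported ground
truth, so the full pipeline is testable end to end without any external
data.

## Worked example

Simulate three 180-min ethograms from a known model, fit the HMM, decode,
and summarise; then detect the coupling onset in simulated calorimetry:

```r
library(coldstate)

sim <- simulate_ethogram(duration_s = 10800, n_animals = 3, seed = 1)
obs <- lapply(sim$ethograms, encode_observations)
fit <- baum_welch_fit(init_params(3), obs)
fit
#> Baum-Welch fit: 8 iterations, converged (final loglik -48957.61)
#> Categorical HMM: K = 3 states, V = 15 symbols
#> Transition matrix A:
#>       [,1]  [,2]  [,3]
#> [1,] 0.949 0.031 0.020
#> [2,] 0.048 0.920 0.032
#> [3,] 0.053 0.030 0.917

map <- assign_semantic_labels(fit$params)
states <- relabel(viterbi_decode(fit$params, obs[[1]]), map)
occupancy_fractions(states)
#>   state  fraction duration_s
#> 1     1 0.4918519       5312
#> 2     2 0.2846296       3074
#> 3     3 0.2235185       2414
mean(states$states == sim$true_states[[1]]$states)
#> [1] 0.9934259

cal <- simulate_calorimetry(seed = 1)
hourly <- lapply(cal$series, hourly_bin, cold_onset_min = cal$cold_onset_min)
prof <- ee_intake_correlation_profile(pool_hourly(hourly))
detect_ciec_onset(prof, threshold = 0.5)
#> CIEC onset: 5 h post cold onset (r >= 0.50 sustained)
```

The fitted transition matrix sits within a few thousandths of the
generator's truth (self-transitions ≈ 0.95), decoding recovers 99% of the
true states, the energy-conservation state dominates occupancy, and the
programmed intake–EE coupling at 5 h post cold onset is found by the
sustained-correlation rule.

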