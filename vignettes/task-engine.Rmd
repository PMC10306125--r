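---
title: "The lickbench task engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lickbench task engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickbench)
```

## What this package simulates

`lickbench` is a desk-scale re-implementation of the control logic of a
head-fixed rodent behavior rig: the 2AFC, Go-NoGo and
passive-stimulation state machines, the trial and delay schedulers, the
session log and settings formats, the 3-byte device command codec, and
the behavioral statistics used to track training. Nothing here touches
hardware; the engine is a pure discrete-event simulation on a virtual
clock, which makes timing exact and every run reproducible from a seed.

The purpose is twofold. First, task logic (randomization constraints,
delay bookkeeping, outcome-dependent scheduling) is exactly the kind of
code that silently drifts on a rig; here it is captured in testable
form. Second, the analysis path (psychometric fitting, d′) can be
validated by *parameter recovery*: a virtual subject with known
parameters generates sessions, and the analysis must get those
parameters back.

## The state machines

**2AFC.** A trial begins with the center spout extending; a lick on it
self-initiates the trial (an analog of fixation in primate tasks).
Initiation licks are rewarded with the configurable "Percentage of
Center Rewards". A prestimulus delay ("Stim Start Delay") precedes the
stimulus; a poststimulus delay ("Time Center Spout Available") follows
it with side spouts still retracted — continued center licking during
this hold can be rewarded ("TCSA reward") as an engagement anchor. The
side spouts then extend and the response window opens; the response
rule requires a configurable number of licks within any 1-s sliding
sub-window (requirement 1 = first lick wins). Correct choices are
rewarded, incorrect ones trigger the punishment event and, in Retrial
Mode, the same stimulus is repeated — the next trial is withheld until
the correct side is licked (capped by "Max Retrials").

**Go-NoGo.** Trials start automatically after the ITI, optionally cued
("Trial Start Signal"). After the stimulus, a "Delay Period" separates
stimulus from response window. A lick is a hit (Go, rewarded) or a
false alarm (NoGo, punished); withholding is a miss or correct
rejection. A correct rejection draws the next ITI from the "Short ITI"
range and — with "CR rule ON" — forces the next trial to be a Go trial,
which counteracts strategic non-licking.

**Passive.** Fixed-count stimulus presentations at a set interstimulus
interval; "Combination" mode cycles the four bar orientations (0°, 45°
left, 45° right, 90°) through a without-replacement pool; multisensory
mode pairs visual and auditory stimuli ordered by "Visual first" with a
configurable onset gap. All on/off edges are emitted as alignment
pulses.

### The delay reference point

The Go-NoGo "Delay Period" timer starts at stimulus **onset** by
default. This is deliberate: a delay table of (min 1, max 5, 6 steps)
with a 200 ms stimulus then produces intervals of 0.8–4.8 s between
stimulus *offset* and window opening, which is the configuration used
for delay-series d′ experiments. A `Delay Reference = "offset"` switch
is provided for protocols that specify the retention interval directly.
The spout's outward travel is scheduled so that it *arrives* exactly
when the delay elapses — the response window can therefore never open
before the spout is in place, and logged offset-to-window intervals
equal the scheduled delays exactly.

## Schedulers

- **Side constraints.** Sides are Bernoulli(p_right) draws, but the
  same side may not occur more than 3 times in a row and there may be
  at most 4 consecutive side switches. "Back-and-forth jumps" is read
  as *consecutive switches*: a streak of s switches is an alternating
  run of s+1 trials, and the 5th consecutive switch is forbidden. A
  conflicting draw is deterministically replaced by the opposite side.
  The two rules can never forbid both sides at once: a run of 3
  identical sides implies the switch streak is 0 (the last transition
  was a repeat), and a streak of 4 switches implies the identical-side
  run is 1 — so the forced side is always legal. This case analysis is
  exercised exhaustively in the tests over all short histories.
- **Delay tables.** `(min, max, steps)` expands to an evenly spaced
  inclusive grid; `steps = 1` yields `[min]` regardless of `max` (the
  single-delay idiom). Values are drawn without replacement and the
  pool reshuffles on depletion, so sampling is exactly equal at cycle
  boundaries; Go and NoGo trials draw from separate pools.
- **ITI.** `min + E` with E exponential truncated to `[0, max − min]`,
  sampled by inverse CDF. The rate is not pinned by any published
  value; the default sets the untruncated mean to `(max − min)/3`,
  which puts ≈95% of the untruncated mass inside the window so the
  truncation bias is small. The rate is an explicit argument.
- **Trial mix.** Psychometric testing mixes 70% training trials
  (columns 0 and 8) with 30% novel-stimulus trials. The mix is
  per-trial Bernoulli by default — that is what a trial-by-trial
  randomizer does — with `exact = TRUE` available to pin the session
  count. Retrial/punishment eligibility is restricted to training
  trials so novel stimuli carry no corrective feedback. The novel pool
  defaults to columns 1–7 (the seven non-training columns); the count
  is configurable rather than hard-coded.

## The virtual subject

The subject is a test harness, not a model of a mouse; no published
generative model of the animal exists, and none is claimed.

- **Choice**: right with probability
  ψ(x) = g + (1 − g − l)/(1 + exp(−(x − α)/β)). The textbook
  four-parameter logistic is used because it is the only bounded
  probability consistent with guess/lapse semantics; `beta = 0` is
  treated as the step-function limit.
- **Go-NoGo responding**: lick probabilities `p_lick_go` /
  `p_lick_nogo`; their quantile difference is the generating d′
  (0.9/0.2 gives 2.12). An optional exponential decay of the rate
  *separation* over the response delay (time constant
  `delay_decay_tau`, default off) emulates performance decay across
  enforced delays — phenomenological only.
- **Licking**: a reaction-time-shifted Poisson burst at
  `lick_rate_hz = 10` (typical rodent licking is ~10 Hz). Reaction
  times are log-normal with median 0.3 s and σ(log) = 0.35 — invented
  plumbing, configurable, roughly matching rodent response latencies.
- **Engagement**: per-trial probability of initiating/responding;
  disengaged trials become no-response outcomes or
  misses/correct-rejections.

What a green recovery test establishes: the engine's bookkeeping and
the analysis code are mutually consistent at realistic trial counts.
What it does not establish: anything about real animals — real lick
trains are bursty and autocorrelated, real lapses drift within
sessions, and real reaction times are stimulus-dependent.

## Analysis

- **Psychometric fit**: binomial maximum likelihood (not least squares
  — column counts are binomial and variance is p(1−p)n), bounded
  parameters (g, l ∈ [0, 0.5], β > 0), deterministic 9-point multistart
  (alpha quartiles × three slope scales) so fits are reproducible
  without randomness. Flat data (range of observed proportions < 0.05)
  raise an `unidentifiable` flag; estimates on the box edge raise
  `boundary_fit`. Probabilities are clipped to [1e−9, 1−1e−9] inside
  the likelihood to keep logs finite.
- **d′**: Φ⁻¹(H) − Φ⁻¹(FA), so that H > FA gives positive d′,
  matching the convention that d′ > 1.5 is *good* performance; rates
  are clipped to [1/(2N), 1 − 1/(2N)] per class before z-scoring
  (configurable), the common log-linear correction for perfect rates.
- **Percent correct**: correct / responded trials; retrial attempts and
  no-response trials are excluded from the denominator by default
  (toggleable) since retrials are training scaffolding, not independent
  choices.
- **Advancement**: 2AFC ≥ 75% correct, or Go-NoGo d′ > 1.5, on each of
  exactly 3 consecutive sessions.

## Logging, codec, DAQ

- The session log is plain text: a `# setting:` header with the full
  configuration, one tab-separated record per event with
  millisecond-precision timestamps, the trial table, and a closure
  footer. Parsing a truncated log flags the result `unclosed` rather
  than failing. Round trips are byte-identical; parsed settings are
  coerced to the storage type of the shipped default per key so types
  survive the trip. (On a real rig such text stamps are only
  ~2–3 ms accurate and unsuitable for neural alignment; the virtual
  clock makes them exact here, but the format keeps the field width.)
- The settings "spreadsheet" export is a single-sheet key/value layout
  written as tab-separated text with an `.xls` extension — spreadsheet
  programs open it transparently, and the deliverable stays plain
  text.
- The 3-byte codec is `[device, assignment, action]`; the only
  externally fixed row is the valve command `['k' 1 1]` (Center,
  open). The rest of `device_command_table()` is package-defined and
  published as the protocol reference.
- Lick debouncing is the greedy pass with a 10 ms lockout (100 Hz
  ceiling). The comparison uses a 1 ns tolerance so that regular lick
  grids (e.g. exact 5 ms steps) are not split by floating-point
  summation error.
- The DAQ trace renders step-function channels at 5 kHz: spout
  channels high while extended, 2 ms lick pulses (within the 5 kHz
  recording bandwidth), LED level encoding the crescent column as
  (column + 1)/10 ∈ {0.1, …, 0.9} (0 = off; nine equally spaced,
  invertible levels — a package convention, documented bit-exactly so
  traces are decodable), reward levels low/medium/high for
  left/center/right, and a punishment gate.

## Numerical and degenerate-input choices

- `steps = 1` delay tables ignore `max`; `min = max` ITIs return the
  constant; empty pools and empty stimulus sets are `invalid-config`
  errors, not silent defaults.
- The moving-bar frame period is not externally specified; default
  30 ms, configurable.
- Tone synthesis uses the 32-point lookup table with linear
  interpolation, as the firmware does; at 192 kHz ≥99% of tone power
  falls within ±2% of the nominal pitch (asserted by test).
- The 2AFC initiation timeout defaults to 30 s; the response window to
  2 s; both configurable — the non-initiating case is not specified
  anywhere authoritative.
- All randomness flows from one session seed through named sub-streams
  (`sides`, `delays`, `itis`, `mix`, `subject`, `rewards`, `stimuli`),
  so adding draws in one component never perturbs another.

## Known limitations

- No learning rule: learning curves are emulated by scripting
  per-session subject parameters, not by plasticity.
- No wall-clock execution: a real-time adapter would be a shim around
  the same engine, but none is shipped.
- No hardware I/O, sound-pressure or luminance calibration, and no
  video-based lick validation.
- The exact pixel art of the stationary-bar patterns is a package
  convention (shipped as a versioned pattern table); analyses depend
  only on stimulus identity.
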