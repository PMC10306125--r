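# lickbench

A hardware-free engine for simulating and analyzing head-fixed rodent
licking tasks.

Head-fixed preparations run three workhorse paradigms: the
two-alternative forced choice task (2AFC — the mouse self-initiates on a
center spout and reports a left/right decision on side spouts), the
Go-NoGo task (lick on Go, withhold on NoGo), and passive sensory
stimulation. Real rigs couple these state machines to moving lick
spouts, LED-matrix and tone stimuli, solenoid valves, and a serial
protocol to a microcontroller. `lickbench` re-implements the whole
control stack as a discrete-event simulation on a virtual clock, plus a
stochastic virtual subject, so that schedulers, state machines, logging
formats and the behavioral statistics can be developed and tested on a
desk — and so that the analysis pipeline can be validated end-to-end by
parameter recovery on data whose generating parameters are known.

It is aimed at behavioral/systems neuroscientists who build or maintain
such rigs and want the task logic and their analysis code under test.

## The models at the core

**Psychometric choice.** 2AFC choice follows the four-parameter
logistic

ψ(x) = g + (1 − g − l) / (1 + exp(−(x − α)/β))

where x is the stimulus position (LED column 0–8, left to right), α is
the curve location (the subject's category boundary), β the
discrimination sensitivity, and g and l the guess and lapse rates.
`fit_psychometric()` estimates all four by binomial maximum likelihood
with a deterministic multistart.

**Signal detection.** Go-NoGo sensitivity is

d′ = Φ⁻¹(H) − Φ⁻¹(FA)

with hit rate H and false-alarm rate FA clipped to [1/(2N), 1 − 1/(2N)]
per class; positive d′ means H > FA.

**Scheduling.** Sides are Bernoulli draws constrained so the same side
never appears more than three times in a row and alternation never
exceeds four consecutive switches; delays are drawn from evenly spaced
(min, max, steps) tables randomly *without replacement* until the pool
is exhausted, then reshuffled; ITIs follow a truncated exponential
inside a (min, max) window; psychometric testing mixes 70% training and
30% novel-stimulus trials.

## Worked example

Simulate one psychometric-testing session (600 trials, 70/30
training/novel mix) for a subject with α = 4, β = 0.8, g = l = 0.05,
then recover the curve:

```r
library(lickbench)
cfg  <- session_config("2afc", `Number of Trials` = 600L,
                       `Fraction Training` = 0.7)
subj <- subject_params(alpha = 4, beta = 0.8, guess = 0.05, lapse = 0.05)
res  <- run_session(cfg, subj, seed = 42)
summarize_session(res)
#> <session 1: 91.3% correct, 600 trials>
fit_psychometric(percent_right_by_column(res))
#> <psychometric_fit alpha=3.711 beta=0.841 g=0.051 l=0.038 logLik=-162.72>
```

The session is 91.3% correct because most trials show the easy training
columns 0 and 8; the fitted curve recovers the generating parameters
(α̂ = 3.71 vs 4, β̂ = 0.84 vs 0.8) from a single session's worth of
novel-column data. A Go-NoGo session and its advancement check:

```r
gng <- run_session(session_config("gng", `Number of Trials` = 300L),
                   subject_params(p_lick_go = 0.9, p_lick_nogo = 0.2),
                   seed = 42)
summarize_session(gng)
#> <session 1: 82.7% correct, d'=1.99, 300 trials>
advancement_criterion(c(1.9, 1.8, 2.0), "gng")   # > 1.5 for 3 days
#> [1] TRUE
```

d′ ≈ 1.99 matches the generating rates (Φ⁻¹(0.9) − Φ⁻¹(0.2) = 2.12)
within sampling error. Sessions round-trip through the plain-text log
(`write_session_log()` / `parse_session_log()`), export their settings
sheet, and render the DAQ-style multichannel trace
(`render_daq_trace()`).

A command-line front end is shipped in `inst/cli/lickbench`:

```sh
Rscript -e 'lickbench::run_cli()' --task gng --seed 3 --out out/
Rscript -e 'lickbench::analyze_cli()' --log out/session.txt --report out/
```

## Documentation

The methods vignette (`vignettes/task-engine.Rmd`) describes the state
machines, every tunable parameter with units and defaults, what the
virtual subject does and does not emulate, and the numerical choices
(fit multistart, rate clipping, debounce tolerance, delay reference
point).
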