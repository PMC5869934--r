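# swayid

Closed-loop system identification of human stance control.

Standing upright is an act of continuous feedback control: the body,
mechanically an inverted pendulum pivoting about the ankles, is pulled
away from vertical by gravity (torque gradient *mgh*) and stabilised by
the nervous system from proprioceptive, visual and vestibular information.
Posturography probes that loop by rotating the support surface with a
pseudorandom ternary sequence (PRTS) and measuring the evoked body sway.
`swayid` implements the full analysis chain for such experiments, for
researchers in sensorimotor control and balance rehabilitation who want to
simulate, identify and fit the independent-channel (IC) stance model:

* **Perturbation design** — maximal-length ternary sequences (80 states,
  20 s period for the four-stage register), integrated and scaled to
  peak-to-peak platform amplitudes; power confined to odd harmonics of
  0.05 Hz so the silent even harmonics screen for nonlinearity.
* **Synthetic trials** — time-domain Runge–Kutta simulation of the closed
  loop `J·θ̈ = mgh·θ + T + d(t)`, with a PD controller `K_P + K_D·s` acting
  through a lumped delay `τ_D` on the weighted sensory error, low-pass
  positive force feedback `K_F/(τ_F·s + 1)`, and pink (1/f) disturbance
  torque; study-structured datasets (0.5°/1° × eyes open/closed, six
  20-s periods per trial).
* **Non-parametric identification** — frequency response function
  `H(f) = Φ_ss,bs / Φ_ss,ss` and coherence `γ²(f)` at the excited
  harmonics from periodic block averaging.
* **Parametric fitting** — bound-constrained nonlinear least squares on
  the coherence/frequency-weighted residual
  `ε(f) = γ²(f)/(1+f) · |log(H_exp/H_est)|`, recovering
  `(W_p, K_P, K_D, τ_D, τ_F, K_F)` with standard errors from
  `E·(JᵀJ)⁻¹` and time-domain variance accounted for (VAF).

The model's closed-loop sensitivity of sway to platform rotation is

```
H(f) = W_p · NC · TD · BD / (1 − FF · NC · TD + NC · TD · BD)
```

with `BD = 1/(J s² − mgh)`, `NC = K_P + K_D s`, `TD = exp(−τ_D s)`,
`FF = K_F/(τ_F s + 1)`, `s = i 2π f`. Sensory weights satisfy
`W_p + W_vis + W_ves = 1`; eyes closed forces `W_vis = 0`, and with eyes
open only the combined space-referenced weight `1 − W_p` is identifiable.

## Worked example

Simulate a noisy 2-minute eyes-closed trial at 1° peak-to-peak, identify
it, and refit the model:

```r
library(swayid)

anthro <- winter_anthropometry(77.7, 1.79)   # body minus feet, from stature
params <- study_parameters(anthro)[["1_closed"]]
pert   <- prts_rotation(prts_states(4), amplitude_pp = 1, fs = 1000)
trial  <- simulate_closed_loop(params, pert, noise_config(amplitude = 0.6, seed = 42))

frf <- estimate_frf(trial, f_max = 2.05)
frf
#> # A tibble: 21 × 8
#>   freq_hz response            gain phase_deg coherence csd        psd_ss  psd_bs
#>     <dbl> <cpl>              <dbl>     <dbl>     <dbl> <cpl>       <dbl>   <dbl>
#> 1    0.05 1.298534+0.390716i  1.36     16.7      0.993 0.043833… 3.38e-2 0.0625
#> 2    0.15 1.675114-0.143720i  1.68     -4.90     0.980 0.006257… 3.74e-3 0.0108
#> 3    0.25 2.065638-0.958835i  2.28    -24.9      0.983 0.002754… 1.33e-3 0.00703
#> 4    0.35 1.647867-2.324399i  2.85    -54.7      0.960 0.001107… 6.72e-4 0.00568
#> # 17 more rows

attr(frf, "even_fraction_pct")   # nonlinearity screen: ~0.93 % of sway power
fit <- fit_ic_model(frf, anthro, condition(1, "closed"), trial = trial)
fit
#> <ic_fit> 1 deg, eyes closed | cost E = 7.896e-04 | 21 frequencies | converged
#>   W_p   = 0.456 (SEM 0.01)
#>   K_P   = 1001.8 N m/rad = 1.45 mgh (SEM 15)
#>   K_D   = 277.5 N m s/rad = 0.40 mgh s (SEM 4.9)
#>   tau_D = 0.169 s (SEM 0.0036)
#>   tau_F = 23.8 s (SEM 2.4e+02)
#>   K_F   = 1.33e-03 rad/(N m) (SEM 0.013)
#>   VAF = 97.5%
```

Reading the numbers: the generating trial used `W_p = 0.450`,
`K_P = 1000.8` (1.45 mgh), `K_D = 276.1`, `τ_D = 0.170 s` — the fit
returns all four within about 1 % despite the injected noise, with a
time-domain VAF of 97.5 %. The force-feedback pair is the exception:
`τ_F` comes back with a standard error of hundreds of seconds because the
20-s perturbation period carries almost no information below 0.05 Hz, so
only the ratio `K_F/τ_F` is well determined. The gain `1.36` at 0.05 Hz
means 1° of platform rotation evokes 1.36° of sway at that frequency;
coherence near 1 shows the response is dominated by the perturbation, not
the noise.

`tidy(fit)` and `glance(fit)` return the estimates and the one-row fit
summary as tibbles; `autoplot()` methods plot trials, spectral estimates
and fit overlays. The whole study design runs in one call:

```r
report <- run_study(study_config(seed = 1))
report$summary          # per condition: recovery error, VAF, coherence, ...
write_study_report(report, "out/")
```

A thin command-line wrapper with `simulate` / `identify` / `fit` /
`run-study` subcommands is installed at `inst/cli/swayid.R`.

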