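---
title: "Genetic clock circuits: model, design rules, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic clock circuits: model, design rules, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
gate model and its assumptions, the design rules for the waveform-shaping
and counter circuits, the numerical conventions, and - importantly - what
the simulations show does *not* work in this model class. Nothing stated
here as an empirical number comes from anywhere but the package's own
tests and `scripts/acceptance.R`.

## The gate model

Every gene is modelled at the protein level by one ODE,

$$\dot p_i \;=\; \rho_i\, f_i(u) \;-\; \gamma_i\, p_i \;+\; \rho_{0,i},$$

with synthesis rate $\rho_i$, decay rate $\gamma_i$, basal production
$\rho_{0,i}$, and a promoter-activity function $f_i \in [0,1]$ of the
regulator concentrations. A two-stage transcription/translation model
(`txtl_kinetics`, `full_gate_rhs`) is also provided; because mRNA decays
much faster than protein, it reduces to the protein-level form with
$\rho = \alpha\beta/\lambda$ and $\rho_0 = \alpha_0\beta/\lambda$
(`reduce_kinetics`), and both share their steady states exactly (this is a
unit test).

With operator-site occupancies $x_i = (u_i/K_i)^{n_i}$, the seven gate
kinds are

| kind | $f$ |
|---|---|
| NOT | $1/(1+x_1)$ |
| Buffer | $x_1/(1+x_1)$ |
| AND | $x_1x_2/Z$ |
| OR | $(x_1+x_2+x_1x_2)/Z$ |
| XOR | $(x_1+x_2)/Z$ |
| NAND | $(1+x_1+x_2)/Z$ |
| NOR | $1/Z$ |

with $Z = 1+x_1+x_2+x_1x_2$. The complementarity identities
($f_\mathrm{NOT}+f_\mathrm{Buffer}=1$, $f_\mathrm{NAND}=1-f_\mathrm{AND}$,
$f_\mathrm{NOR}=1-f_\mathrm{OR}$,
$f_\mathrm{XOR}=f_\mathrm{OR}-f_\mathrm{AND}$) hold algebraically and are
asserted to $10^{-12}$ *absolute* on random inputs - absolute rather than
relative, because at extreme occupancies ($x \sim 10^{20}$) the
subtraction $1-f$ in the reference expression underflows while the direct
form is exact.

Assumptions worth keeping in mind: deterministic mass-action-style
kinetics (no molecular noise), instantaneous transcription-factor binding
(quasi-equilibrium Hill functions), no resource competition between genes,
and no delay terms. Concentrations are dimensionless arbitrary units, time
is in seconds. Hill coefficients need not be integers; all bundled
circuits use $n = 4$.

## The repressilator clock source

`build_repressilator()` wires three NOT gates in a ring
(`p_lacI -| p_tetR -| p_cI -| p_lacI`) with synthesis 0.6851, decay 0.233,
$K = 1$, $n = 4$, initial concentrations $(0.7, 1.2, 1.7)$, and a
regulation coefficient $\chi$.

**Where $\chi$ acts is a genuine design choice**, and the package keeps
both readings behind `chi_scaling`:

* `"whole"` (default): $\dot p = \chi\,(\rho f - \gamma p)$. This is a pure
  rescaling of time - halving $\chi$ exactly doubles the period while the
  waveform shape, amplitude and base level are untouched. The product
  $\mathrm{period}\times\chi$ is constant across a sweep (a unit test).
* `"synthesis"`: $\dot p = \chi\rho f - \gamma p$. This moves the
  nullclines; with the default rates the Hopf oscillation dies below
  $\chi \approx 0.8$, so at $\chi = 0.5$ the ring settles to a fixed point.

The default was fixed by a calibration test: only the whole-rhs reading
oscillates at $\chi = 0.5$ at all, and it does so with a basal period of
32.3 s - the 32 s operating point the rest of the package builds on.

At $\chi = 0.5$ the steady waveform of any of the three species spans
$[0.631, 1.900]$: amplitude (half peak-to-trough) 0.6345, mid peak-trough
level 1.2655. Note a subtlety: the *reference sinusoid* the bundled shaper
designs were derived against has amplitude 0.63 but base level 1.1731.
The simulated ring matches the reference amplitude closely but sits about
0.09 higher; its steady range is fixed entirely by $(\rho, \gamma, K, n)$,
and no placement of $\chi$ can move it (time rescaling does not change a
waveform's range). The consequences for the narrow-pulse design are
discussed under Limitations.

## Waveform shaping: from rhythm to clock pulse

A Buffer's steady response to a constant input is
$p_{ss}(u) = (\rho/\gamma) f_\mathrm{Buffer}(u;K,n) + \rho_0/\gamma$ -
sigmoidal, half-way between its floor and ceiling exactly at $u = K$, so
$K$ *is* the stage's threshold. Cascading Buffers repeatedly squashes the
signal toward the rails; each pass through a stage with operating-point
gain

$$A = \frac{\rho\, n}{4\,\gamma\, K} > 1$$

steepens the transition. `design_cascade()` implements the recursion: the
first stage thresholds the oscillation at a chosen $y_T$, every later
stage at half the previous stage's ceiling,
$K_k = (\rho_{k-1}+\rho_{0,k-1})/(2\gamma_{k-1})$ (0.5 for unit rates). A
final compensation Buffer with synthesis rate
$\rho = \gamma\, t_\mathrm{high} / f_\mathrm{Buffer}(u_\mathrm{high};K,n)$
(`compensation_rate`) lifts the logic-high plateau back to its nominal
level when a large first threshold leaves the cascade short of it.

Two ways to pick the first threshold for a target duty cycle $D$:

* `analytic_threshold()`: for an ideal sinusoid with amplitude $A$ and
  base $y_0$, the level exceeded during exactly the fraction $D$ of a
  cycle, centred on the peak, is $y_T = y_0 + A\cos(\pi D)$. (A printed
  closed form for the peak time in our source material for this formula is
  garbled; the implementation takes the peak time as the phase where
  $\omega_0 t + \varphi = \pi/2$, the only reading under which the two
  half-on-time evaluations around the peak coincide in a single
  threshold.) It is continuous and strictly decreasing in $D$, with limits
  $y_0 + A$ as $D \to 0$ and $y_0 - A$ at $D = 1$.
* `empirical_threshold()`: the repressilator waveform is *not* sinusoidal
  (fast rise, slow decay), so the closed form is biased on real traces.
  The empirical variant takes the steady-window time-quantile: the level
  above which the signal spends exactly the fraction $D$ of its time. On
  an exact sinusoid the two agree (a unit test).

The gain condition is reported, not enforced: `check_gain_condition()`
warns about stages with $A \le 1$. The bundled narrow-pulse design
needs a first threshold of 1.76, whose gain is $4/(4\cdot 1.76) = 0.568$;
the design still functions because the four downstream stages (gain 2)
supply the sharpening, so rejecting the design outright would be wrong.
This is deliberately a warning, with the threshold choice left to the
user.

Three reference designs ship with the package
(`shaper_reference_design`): a narrow pulse (first threshold 1.76,
compensation rate 1.0872), a wide pulse (0.6761, 1.1083), and a rectifier
("dc": all thresholds 0.5, compensation 1.0851). Driven by the $\chi=0.5$
oscillator they measure, respectively, duty cycles of 13.6%, 89.5% and
100% (ripple 1.5%), all frequency-coherent with the oscillator to well
under 1%.

## Measuring a waveform

All metrics share two conventions. First, the initial 30% of every run is
discarded (`steady_window`) - a conservative allowance for the two to
three settling cycles these circuits exhibit. Second, sub-grid accuracy
comes from interpolation, not from a finer grid: cycle maxima are refined
by a three-point quadratic fit (a 32 s period on the default 0.01 s grid
is recovered to well below one grid step), and threshold crossings are
linearly interpolated, which makes duty cycles accurate to about
$3\times10^{-4}$ of a cycle.

* `measure_period`: mean spacing of one refined maximum per cycle; cycles
  are delimited by hysteresis-filtered upward crossings of the mid-range
  level so that solver ripple on flat pulse tops cannot create spurious
  peaks. Signals whose steady swing is below 1% of their level raise a
  no-oscillation error rather than returning nonsense.
* `measure_duty_cycle`: time-fraction spent at or above a threshold; the
  default threshold is the mid-range level (symmetric and
  parameter-free). A signal whose swing is below 5% of its level is
  classified as a logic-steady (DC) level and reports duty 1.0 - the 5%
  band matching what the rectifier design is allowed as residual ripple.
  With an explicit threshold the comparison is always literal.
* `detect_edges`: interpolated crossing times with a hysteresis band
  (default 5% of the steady swing) to suppress chatter; rising and
  falling edges strictly alternate by construction.

Halving the solver tolerances moves these metrics by less than 0.1%
(convergence test), and they are invariant to time shifts and scale
correctly under signal rescaling (property tests).

## Sequential logic: flip-flops and counters

The rising-edge JK flip-flop is six genes: `W = AND(K, CLK)`,
`V = AND(J, CLK)`, `R = AND(W, Q)`, `S = AND(V, Qb)` and a cross-coupled
NOR latch `Q = NOR(R, Qb)`, `Qb = NOR(S, Q)`. Driven by a narrow clock
pulse it samples J and K once per low-to-high transition; with constant
logic inputs it reproduces the full digital JK table
(hold/reset/set/toggle) against an independent four-state digital
simulator over 8 clock cycles - for both initial states. The falling-edge
variant replaces every gate by NAND and is exercised by a wide clock
(short low window).

Defaults mirror the reference counters: $\rho=\gamma=1$, $\rho_0=0$,
$K=0.5$, $n=4$ for every gene, logic-1 inputs as constant sources at
level 1.0. Flip-flop initial conditions are not part of the printed
designs; the package seeds a consistent latched 0 (Q at 0, Qb at its
ceiling $\rho/\gamma$, all other genes at 0), overridable by editing the
returned `circuit_spec`.

`build_binary_counter(delta)` chains rising-edge flip-flops on one clock:
ff1 toggles every pulse (J=K=1), ff2 is fed by `ff1.Q`, and stages three
onward by carry AND genes. `build_mod3_counter()` combines two
rising-edge and one falling-edge flip-flop with an OR output gene.
Species are prefixed (`ff1.Q`, `ff2.Qb`, ...) so composed circuits stay
unambiguous.

## Numerical choices

* Integration: `deSolve::ode` with `lsoda` (stiff-capable, automatic
  switching), `rtol = 1e-8`, `atol = 1e-10`; results are required to be
  method-independent within tolerance.
* Output grid 0.01 s for 32 s-period signals (at least 3200 samples per
  cycle, duty-cycle quantisation below 0.1 percentage point); the long
  counter runs use 0.02 s, which still oversamples a 64-128 s output by
  three orders of magnitude.
* Regulator levels are clamped at zero before Hill evaluation (fractional
  $n$ on a tiny negative undershoot would produce NaN); the linear decay
  term sees the raw state, and clipping to zero happens only in the
  reported trace.
* Activities at $u = 0$ are evaluated by limit ($x = 0$), avoiding $0^n$
  for non-integer $n$.
* Square-wave drives use a 0.2 s linear edge - sharp against a 32 s
  period, kind to the step-size controller.
* Problem sizes: oscillator and shaper runs are 500 s (about 15 cycles,
  10 of them measured); the composed counter chains run 1200-1500 s
  (21 and 34 species) so the slowest intended output would still show
  at least three steady cycles.

## Limitations, and what the model class itself shows

Passing tests here validate the *model's* behaviour, not wet-lab
feasibility: no noise, no loading effects, no parameter uncertainty. More
interestingly, three of the package's own end-to-end checks fail *by
faithful simulation*, and the failures are informative:

1. **The narrow-pulse reference design misses its 10% target.** Its first
   threshold (1.76) was derived against the reference sinusoid
   (base 1.1731, peak 1.803). The simulated oscillator peaks at 1.900
   with base 1.2655, spends 18.3% of each cycle above 1.76, and the
   shaped pulse measures 13.6% - outside a 10±2 percentage-point band.
   The design pathway, not the constant, is the fix: an
   `empirical_threshold` for $D = 0.1$ on the actual trace lands near
   1.86. The wide-pulse and DC designs are insensitive to this offset and
   meet their targets.
2. **The binary counter divides by 2 but not by 4.** ff1 (constant
   J=K=1) toggles cleanly: its output period is 64.6 s against a 32.3 s
   clock. ff2's J/K input is `ff1.Q` itself, and therein lies a race: the
   clock pulse that should toggle ff2 is the same pulse that flips
   `ff1.Q` (in about 3 gate time-constants), truncating the drive to
   ff2's set gene, which peaks just above its own threshold (about 0.58
   against $K=0.5$) - too weak to carry the NOR latch past its
   separatrix, so `ff2.Q` rises to about 0.4 and collapses. A sweep over
   pulse shapes shows divide-by-4 emerging only for pulses at least 5 s
   wide *and* 1.1 high - outside what any Buffer cascade with unit rates
   can deliver (gate ceilings are $f_\mathrm{AND}(1,1) \approx 0.89$).
   Edge-triggered (master-slave) flip-flops exist in electronics
   precisely to eliminate this race; the pulse-triggered genetic topology
   has no such protection.
3. **The printed falling-edge variant is only a toggle element.** With
   J=K=1 it divides by two exactly as intended, but for J or K low the
   NAND network is not a latch at all (e.g. J=K=0 forces Q high through
   `S = NAND(V=1, Qb)`), so hold/reset/set fail against the digital
   oracle. The mod-3 counter wires its falling-edge stage with dynamic
   J/K, inheriting both this defect and the race above; its output gene
   stays near logic-high with small ripple instead of completing one
   cycle per three. The constructors implement the printed equations
   verbatim rather than silently "repairing" them - the point of a
   faithful implementation is that such analyses become possible.

These findings are reproduced by `tests/testthat/test-acceptance.R`
(the corresponding expectations are intentionally left failing) and the
numbers by `scripts/acceptance.R`.
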