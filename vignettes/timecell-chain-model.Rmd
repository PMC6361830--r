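---
title: "A chain model of time cells with scalar timing variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chain model of time cells with scalar timing variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(timecellr)
```

## The model

`timecellr` simulates a feedforward chain of *time cells*: neurons that
fire sequentially during a timed interval, so that the identity of the
currently active cell encodes elapsed time. Each cell is a spikeless
integrate-and-fire unit,

$$C_m \frac{dv}{dt} = -\big(I_L + I_D + I_{Exc} + I_{Inh}\big) + I_{input} + I_{noise},$$

with a leak current $I_L = g_L (v - E_L)$, a slowly inactivating D-type
potassium current

$$I_D = g_D\, m_d\, h_d^2\, (v - E_K), \qquad
  \dot m_d = \frac{m_{d\infty}(v) - m_d}{\tau_m}, \quad
  \dot h_d = \frac{h_{d\infty}(v) - h_d}{\tau_h},$$

synaptic excitation $I_{Exc} = (g_{Exc}\, s_{pre} + g_{Excr}\, s_{self})(v - E_{Exc})$,
and a slow inhibition $I_{Inh} = N g_{Inh} (v - E_{Inh})$ whose strength
grows linearly with the number $N$ of cells that have already fired. A
spike is an event: when $v$ reaches the threshold $V_T$ the potential is
reset to $v_R$ and the cell's synaptic variable $s$ jumps to 1, decaying
between spikes as $\dot s = -\beta s$. No action-potential waveform is
synthesized.

The timing mechanism lives in the interplay of three ingredients:

1. **The D-current is primed at rest.** Its inactivation gate
   $h_{d\infty}(v) = 1/(1+e^{v+65})$ sits near 1 for a hyperpolarized
   cell, so the hyperpolarizing brake $I_D$ is fully charged before a cell
   receives excitation.
2. **Excitation must outlast the brake.** When sustained drive arrives,
   the cell depolarizes to a sub-threshold balance and waits while $h_d$
   decays with the slow time constant $\tau_h$ (1.5 s by default). The
   spike fires when $g_D m_d h_d^2 (V_T - E_K)$ has decayed below the
   *firing margin* — the excess of synaptic drive over leak plus
   inhibition at threshold.
3. **Inhibition accumulates.** Every newly activated cell adds
   $g_{Inh}$ to the common inhibitory conductance, shrinking the next
   cell's margin. Later cells therefore need $h_d$ to decay further, and
   because exponential decay is slow in its tail, the inter-activation
   intervals (ISIs) lengthen super-linearly while small perturbations are
   amplified ever more strongly.

A chain run is started by a stimulus to cell 1; each newly active cell
fires persistently through its recurrent excitation, drives its successor
through the feedforward synapse, and is silenced when the successor first
fires (its recurrent input is cleared; its synaptic variable decays
naturally, so the successor still sees a fading tail).

## Parameters and the published table

The default constants follow the published set: $C_m = 200$, $g_L = 8$,
$E_L = -65$, $g_D = 4$, $E_K = -90$, $\tau_m = 0.6$ ms, $\tau_h = 1500$ ms
(3000 ms in the chain-wave experiment), $V_T = -50$, $v_R = -85$,
$v_{init} = -75$, $g_{Excr} = 50$, $E_{Exc} = 0$, $\beta = 0.2$ ms$^{-1}$,
$g_{Inh} = 0.02$, $E_{Inh} = -100$, stimulus amplitude 4. The published
unit labels are mutually inconsistent (µS conductances against µF/cm²
capacitance and mA/cm² currents), so the package treats all quantities as
one consistent arbitrary-unit system and uses the numerals verbatim.

Three published values could not be used as printed, because they are
provably incompatible with the dynamics the model is meant to produce.
The package re-anchors them once, as follows.

**The stimulus is conductance-typed.** An input *current* of amplitude 4
can never fire the cell: with $g_L = 8$ the most depolarized attainable
balance is $(g_L E_L + 4)/g_L \approx -64.4$ mV, far below threshold, for
every inhibition level. Read as an excitatory *conductance* step of
amplitude 4 (reversal $E_{Exc} = 0$), the same printed constants
reproduce the published single-cell delays almost exactly (see the worked
example below). `stimulus_protocol(type = "current")` retains the
current-typed variant.

**The feedforward conductance.** The published $g_{Exc} = 15$ races: a
persistently firing cell holds $s \approx 0.8$–1, so the successor
receives an effective drive of ~12 conductance units, which dwarfs the
maximal D-current brake ($g_D (V_T - E_K) = 160$ current units) and
eliminates delayed firing altogether — the wave crosses 40 cells in a few
hundred milliseconds with constant ISIs. The single-cell experiment pins
the operative drive at about the stimulus amplitude (4): that is the
regime in which inhibition levels $N = 20$–60 modulate the delay between
0.6 and 1.2 s. The default $g_{Exc} = 5.5$ delivers that drive
($\bar s \cdot g_{Exc} \approx 4.4$) while keeping the firing margin of
the 60th cell at ~40% of the first cell's margin, so the default chain
propagates end-to-end robustly under trial noise. The chain then takes
~45 s to traverse 60 cells with ISIs growing from ~0.4 s to ~1.25 s.

**Noise magnitudes.** The published conductance SDs (1 for $g_D$, 5 for
$g_{Exc}$) translate into margin perturbations several times larger than
the entire width of the delayed-firing regime; virtually every trial's
wave would die mid-chain. The defaults keep the published 1:5 ratio but
scale both SDs by a common factor into the regime the full chain can
absorb: `sd_gD = 0.03`, `sd_gExc = 0.15` (about 1% and 3% relative
noise). Similarly, a bombardment conductance of 1 with 100 presynaptic
units at 50 Hz ($\beta_n = 0.1$) would add a *mean* excitatory
conductance of ~33 units — four times the leak conductance; the
package's reference value `g_noise_ref()` = 0.005 caps the mean
bombardment drive at a small fraction of the firing margin, and the
bombardment sweep scans 0.6–1.2 times this reference, preserving the
published relative sweep.

## Noise structure: why trial-level draws

`noise_config(draw = "per_trial")` (the default) draws one
$g_D \sim \mathcal N(g_D, \sigma_D)$ and one
$g_{Exc} \sim \mathcal N(g_{Exc}, \sigma_E)$ per trial, shared along the
chain; `draw = "per_cell"` gives every cell an independent draw.

The distinction decides whether the scalar property can emerge. The time
to the $k$-th activation is a sum of $k$ ISIs. If each ISI is perturbed
independently (per-cell draws, or fast bombardment noise), the SD of the
sum grows like $\sqrt k$ while the mean grows like $k$ — the classic
square-root compression, and the CV *falls* along the chain. A trial-level
conductance offset, in contrast, shifts *every* ISI coherently, and by an
amount that grows with the cell index, because the late cells' firing
margin $M_k$ has been eroded by accumulated inhibition: the delay responds
to a drive perturbation as $\delta\,\mathrm{ISI}_k \propto \delta g / M_k$.
This sensitivity amplification is exactly the model's verbal mechanism —
"late stages of a slow exponential decay are most sensitive to
perturbation" — and it makes the spike-time SD grow in proportion to the
mean. With the default noise the measured CV is ~0.10 and varies by only
a few percent between cell 10 and cell 60, the SD-versus-mean line has
$R^2 > 0.99$, and mean-normalized spike-time histograms of different
cells superpose. Per-cell draws are retained deliberately: running them
shows the CV falling several-fold along the chain, the contrast that
makes the emergence claim meaningful.

The same logic explains a genuine limitation: with bombardment as the
*only* noise source the CV level rises with `g_noise`, but the CV still
falls along the chain at every feasible level — fast noise decorrelates
across ISIs, and no within-trial-independent perturbation can escape the
square-root compression. The package reports this honestly rather than
reproducing the published claim of a flat CV under bombardment-only
noise.

Two further analytic/Monte-Carlo nulls quantify the compression that the
chain escapes: `sum_of_normals_null()` (identical independent ISIs:
CV $\propto 1/\sqrt N$) and `increasing_isi_null()` (independent ISIs
with growing means and per-ISI scalar noise: the cumulative CV still
falls). Lengthening ISIs alone are not sufficient for scalar timing; the
trial-correlated sensitivity is what does the work.

## Numerical scheme

The integrator (C++, fixed step `dt = 0.05` ms) advances the membrane
potential by explicit Euler and the gates by exact exponential relaxation
toward their voltage-frozen targets, which handles the stiffness between
$\tau_m = 0.6$ ms and $\tau_h$ of seconds; synaptic variables decay by the
exact factor $e^{-\beta\,dt}$. A spike is detected at the first step with
$v \ge V_T$, with no sub-step interpolation. Consequences, measured:

* the leak-only trajectory matches its closed form to better than 0.1 mV;
* single-cell delayed-firing spike times move by well under 1 ms when
  `dt` is halved;
* chain spike times converge only in relative terms (~1% per halving),
  because the ~2 ms persistent-firing cycle of the active cell is
  quantized at step resolution, which slightly shifts the effective
  feedforward drive. This is inherent to threshold detection without
  interpolation and is documented rather than hidden.

Gates and synaptic variables are provably confined to $[0,1]$ by the
relaxation updates; every simulation returns the observed global range as
a runtime check. All randomness — conductance draws in R, bombardment
events inside the integrator — flows from R's RNG, so one `set.seed()`
reproduces a run bit-exactly.

When every cell shares one parameter draw and bombardment is off, all
cells beyond the wavefront's successor are in bit-identical states (zero
synaptic input, common inhibition), and the integrator collapses them
into a single waiting-pool template. The fast path performs the same
arithmetic per tracked cell and is asserted bit-exact against the full
loop in the test-suite; it makes a 60-cell, 45-simulated-second trial run
in ~0.05 s, which is what allows 200-trial statistics and full parameter
sweeps inside a test run.

## Worked example

The single-cell delayed-firing protocol is one continuous 10 s
simulation under three levels of imposed inhibition, with a sustained
step drive starting 1 s into each 3 s window:

```{r fig2}
res <- run_fig2_single_cell()
res$delays
```

The delays (about 695, 883 and 1366 ms at $N$ = 20, 40, 60) bracket the
published "about 600, 800 and 1,200 ms", increase strictly, and increase
by growing increments — the super-linear signature of timing by a slow
exponential decay. The `h_d` trace in `res$trajectory` shows the
inactivation gate ticking down during each delay.

The deterministic chain wave (40 cells, $\tau_h$ = 3000 ms):

```{r fig3}
rec <- run_fig3_chain(n_cells = 40, h_dtau = 3000)
head(activation_isi(rec))
tail(activation_isi(rec))
plot(rec)
```

Multi-trial statistics under the default trial-level conductance noise
(60 cells; 200 trials is the reference condition, 50 shown here):

```{r trials}
ts <- run_trials(network_config(n_cells = 60), noise_config(),
                 n_trials = 50, base_seed = 1)
st <- scalar_stats(ts, fit_cells = 10:60)
st
plot(st)
nh <- normalized_histograms(ts, cells = c(30, 40))
nh$ks
plot(nh)
```

And the null contrast:

```{r nulls}
sum_of_normals_null(4, 1000, 100)
head(increasing_isi_null(100 * (1:10), 0.1, n_draws = 2000))
```

## Problem sizes used by the packaged experiments

The test-suite and the acceptance script use: the full 200-trial, 60-cell
condition for the headline statistics; 50 trials per value for the
$\tau_h$ and $g_D$ sweeps (60 cells) and the bombardment sweep (40
cells); and reduced chains (3–12 cells) for structural and numerical
checks. These sizes are the package's own choices for routine
reproducibility; the protocols scale to larger runs through their
arguments.

## What the synthetic experiments do and do not show

The generator emulates the model's own study conditions: identical cells,
a clean chain topology, stationary trial-level conductance noise, and
optional Poisson bombardment. It does not emulate heterogeneous cell
populations, ensemble-size effects, synaptic plasticity, conduction
delays, or any recorded data; passing tests therefore validate the
mechanism and its statistical signature, not a fit to biology. Known
limitations worth restating: the capacity of the clock is bounded by the
margin erosion (with the defaults the wave stalls near $N \approx 100$
accumulated inhibition units); the ISI direction of the $g_D$ effect
opposes the published verbal description (the equations make larger
$g_D$ a stronger brake, hence longer ISIs, while the published prose
claims the reverse; the CV direction — smaller asymptotic CV for larger
$g_D$ — does hold); and bombardment-only noise cannot yield a flat CV,
as discussed above.
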