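---
title: "Representational switching by short-term plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational switching by short-term plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stpnet)
```

## The circuit and the phenomenon

`stpnet` simulates a minimal prefrontal-cortex circuit that plans an action
from a displayed goal.  Four excitatory populations A--D (200 conductance-based
leaky integrate-and-fire neurons each at full size) and one inhibitory
interneuron pool (IN) are wired so that two *goal assemblies* (A&B and C&D)
and two *action assemblies* (A&D and B&C) share neurons pairwise.  Goal
assemblies are internally coupled by depressing synapses, action assemblies
by facilitating synapses; self-recurrent connections and all synapses to and
from the interneurons are non-plastic ("constant").

When a goal is displayed, a sensory pulse ignites the corresponding goal
assembly and the network holds that goal as persistent activity.  Sustained
firing then *depresses* the goal assembly's internal synapses while
*facilitating* the cross-links to the action assemblies, so on a timescale
of roughly a second the dominant cell assembly -- and with it the attractor
landscape -- is handed from the goal pair to an action pair.  The network's
activity switches from encoding the goal to encoding one of the two possible
actions without any external trigger.  This endogenous representational
switching, observed in primate lateral prefrontal neurons during
goal-oriented action planning, is the phenomenon every component of this
package quantifies.

## Spiking model

Each neuron integrates

$$C_m \dot V = -g_L (V - V_L) - g_E(t)\,(V - V_E) - g_I(t)\,(V - V_I) + \eta,$$

with threshold $-52$ mV, reset $-60$ mV, excitatory/inhibitory reversals
$-5$/$-75$ mV; excitatory cells have $C_m = 0.5$ nF, $g_L = 25$ nS,
$V_L = -70$ mV and a 2 ms refractory period, interneurons $0.2$ nF, $20$ nS,
$-65$ mV and 1 ms.  Each synapse class from population $l$ to $k$ carries a
*summed* weight $W_{kl}$; every neuron receives exactly $cN$ presynaptic
partners per incoming class ($c = 0.2$), each of per-synapse weight
$W_{kl}/(cN)$, with a transmission delay drawn uniformly from 1--5 ms.
Synaptic activity $s$ (the open-receptor fraction) is a presynaptic-neuron
quantity: a spike sets it to its peak and it decays exponentially with
$\tau_s = 100$ ms for excitatory (NMDA-like) and 20 ms for inhibitory
synapses.  Constant synapses peak at 1; plastic synapses peak at $u\,x$
under the Tsodyks--Markram event rule

$$u \leftarrow u + U(1-u), \qquad s \leftarrow u\,x, \qquad x \leftarrow x - u\,x,$$

with $U = 0.2$ and relaxation $\dot u = (U-u)/\tau_u$, $\dot x =
(1-x)/\tau_x$ between spikes.  Depressing synapses use $\tau_u = 20$ ms,
$\tau_x = 600$ ms (resources deplete under sustained firing); facilitating
synapses use $\tau_u = 600$ ms, $\tau_x = 100$ ms (utilization stays
elevated, resources recover quickly), so facilitation is strongest at
moderate rates.  The four printed recovery constants admit only this
assignment that yields net depression and facilitation respectively; it is a
reconstruction, stated here once.

The three network variants are parameterized by their summed weights
(goal / action / self / E-to-IN / IN-to-E, in nS): `all_types`
3.2 D / 1.55 F / 1.7 C / 0.7 C / 5 C, `depression_only`
3 D / 0.5 C / 1.8 C / 0.7 C / 5.5 C, and `facilitation_only`
0.8 C / 3.1 F / 1.9 C / 0.7 C / 7.5 C.  The canonical YAML files under
`inst/extdata/` encode these tables exactly.

Integration is hybrid: fixed-step 4th-order Runge--Kutta at $dt = 0.1$ ms
for the membrane equation with conductances held across the step, exact
exponential relaxation for $s$, $u$, $x$, threshold detection after each
step (spikes timestamped at step end, reset applied, refractory entered),
and delays quantized to integration steps and served from a ring buffer.
A compiled core carries the per-step work; an independent scalar
event-driven reference in the test suite must agree spike-for-spike on
noise-free fixtures.

### Stimuli and trial timeline

The goal display begins at 0.5 s.  From its onset a common *activation*
conductance ramps linearly to 0.35 nS over 200 ms on all four excitatory
populations and persists to the end of the trial (4 s); a rectangular
*sensory* pulse (0.2 nS, 200 ms) targets the displayed goal's assembly.  An
optional rectangular perturbation pulse can target one action assembly.
The nominal Go cue at 3 s is used only by summaries: the switch must precede
it.  The absolute timeline is the package's own choice; the stimulus widths
and amplitudes are the reference values.

### The membrane noise amplitude

Every neuron receives an independent Gaussian increment of standard
deviation $\sigma\sqrt{dt}$ per step.  $\sigma$ is the one parameter of the
reference parameter set we could not adopt verbatim, so it is calibrated
once, against two stated operating properties: the resting network must stay
essentially silent (excitatory rates below 1 Hz), and the goal state must
survive on the order of a second before the endogenous transition.  At
$\sigma = 0.17\ \mathrm{mV\,ms^{-1/2}}$ the resting excitatory rate is
$\approx 0.1$ Hz and the median goal-axis dwell at full size is
0.6--0.8 s; below
$\approx 0.12$ the sensory pulse fails to ignite the goal assembly reliably,
above $\approx 0.18$ the resting state ignites spontaneously.  The value is
exposed as `noise_sigma` in the configuration and was fixed before the
acceptance analyses were frozen.

### What a trial looks like

```{r}
cfg <- network_config("all_types")        # 200 neurons per population
tr  <- run_trial(cfg, seed = 1)
matplot(tr$time, tr$rates[, 1:4], type = "l", lty = 1,
        xlab = "time (ms)", ylab = "rate (Hz)")
matplot(tr$time, tr$efficacy, type = "l", lty = 1,
        xlab = "time (ms)", ylab = "assembly efficacy (nS)")
```

The goal assembly ignites shortly after the display, its efficacy (the mean
peak conductance its neurons receive from their partner population,
$W \cdot \overline{u x}$ for plastic classes) collapses from 0.64 nS toward
0.1--0.2 nS while the action assemblies' efficacies rise from 0.31 nS toward
0.5--0.6 nS; the dominant-efficacy assembly switches *before* the firing-rate
transition, and the read-outs A1 = A+D, A2 = B+C report the selected action.

In the stochastic network the trajectory occasionally visits the opposing
goal assembly transiently between the goal and action epochs; this
excursion remains on the goal axis of state space (it moves the
first-principal-component projection, not the second), so dwell-time
measurements are unaffected, but it is a visible difference from the
noiseless reduction and from idealized single-trial portraits.

## Mean-field reduction

The reduction tracks, per excitatory population, the mean constant-synapse
activity $\bar s$, the plastic means $\bar u_F, \bar x_F, \bar u_D, \bar
x_D$, and the interneuron activity $\bar s_I$ -- 21 states.  Rates are
algebraic: $r_k = f(g_{E,k} - c_I\, g_{I,k})$ with the Naka--Rushton
transfer $f(g) = r_{\max} [g - \theta]_+^2 / (h^2 + [g-\theta]_+^2)$
(exponent $M = 2$).  Conductances use the same summed weights as the
spiking model with the plastic-class mean activity $\bar s\,\bar u \bar x$
(constant: $\bar s$) -- the mean of activities whose peaks are $u x$ versus
1, so the resting plastic transmission is $U \bar s$.  Mean activities relax
to the stationary value $r\tau_s/(1 + r\tau_s)$ (the time average of
peak-to-one exponential decay under rate-$r$ spiking; exact for Poisson
trains, within 10% for periodic ones) with their own $\tau_s$, and the
plastic means follow the standard rate-driven forms
$\dot{\bar u} = (U-\bar u)/\tau_u + U(1-\bar u) r$,
$\dot{\bar x} = (1-\bar x)/\tau_x - \bar u \bar x r$.

Two reference adjustments are applied exactly as stated for the reduction:
the goal-assembly summed weight is 1.9 nS (the noisy spiking network
transitions earlier than the noise-free reduction, and the reference
compensates by weakening the goal coupling), and, because a perfectly
symmetric noise-free model would sit on the action saddle forever, a small
symmetry-breaking pulse (0.01 nS, 200 ms) is applied to one action assembly
at goal-display onset.

### Fitting the transfer functions

`sample_rate_surface()` measures clamped-pool responses on a conductance
grid, and `fit_rate_function()` fits the Naka--Rushton form by
Levenberg--Marquardt with square-root-scale residuals (the
variance-stabilizing transform for count-derived rates).  Two departures
from a naive clamp-only fit proved necessary and are part of the
calibration protocol (`calibrate_rate_params()`):

* **In-network samples.**  A constant-conductance clamp lacks the recurrent
  synaptic bombardment and partial synchrony of the operating network and
  under-predicts in-operation responses (the interneuron pool fires
  $\sim$10 Hz at drives where a clamped pool is nearly silent).  The
  operating-range parameters $(\theta, h, c_I)$ are therefore fitted to
  exact conductance-rate pairs reconstructed from spiking trials
  (`network_rate_samples()`; the population-mean conductance is linear in
  the recorded mean synaptic activities), over trials spanning rest, goal
  and action regimes and both goals.  The asymptote $r_{\max}$, not
  identifiable from operating-range data, is taken from the clamp-surface
  fit.
* **A quiescence floor.**  Rates below 2--3 Hz are noise-driven
  subthreshold firing that the hard-threshold Naka--Rushton family cannot
  represent; absorbing them into the suprathreshold branch drags
  $\theta$ below the resting drive and destroys the resting fixed point
  that the spiking network demonstrably has.  The calibration censors
  samples below 3 Hz to zero, placing $\theta$ in the empty drive interval
  between quiescent and active operation.

The shipped defaults (`default_rate_params()`) are the output of this
pipeline at the default configuration.  Downstream analyses use the stored
constants, so the reduction and its stability analysis are deterministic.

### Fast--slow stability analysis

The plastic means drift on 0.5--1 s timescales while the synaptic activities
relax within $\le 100$ ms, so $(\bar u, \bar x)$ (and the stimulus) are
frozen and the equilibria of the five-dimensional fast subsystem
$(\bar s_{A..D}, \bar s_I)$ are found by damped Newton--Raphson from a
deterministic 32-seed grid (every on/off pattern of the four populations
times a low/high interneuron guess), deduplicated at $10^{-6}$, and
classified by the eigenvalues of a central finite-difference Jacobian
(step $10^{-6}$; stability margin $10^{-9}$, near-zero real parts flagged
marginal).  Residuals below $10^{-8}$ are enforced by the tests, and every
stability label is cross-checked by perturb-and-relax integration.
`track_attractors()` repeats this along a mean-field trajectory and labels
each equilibrium by its rate pattern (rest / goal / action / mixed).

With plasticity at rest the fast subsystem has exactly three stable
attractors -- the resting state and the two goal states.  Along the default
trajectory the goal attractors are destroyed by the synaptic modulation
shortly after ignition and two action attractors appear; late in the trial
the unoccupied action attractor fades as the facilitation that supported it
decays.  The occupied state always tracks a currently stable attractor.

## Derived measures

* **PC basis** (`fit_pca()`): pooled population rates minus the resting
  rates (pre-display window), uncentred PCA, so rest projects to the
  origin.  With long balanced epochs the first two components are the goal
  and action contrasts by variance; `align = TRUE` relabels and sign-fixes
  the two leading axes against the structural contrasts
  $(1,1,-1,-1)/2$ and $(1,-1,-1,1)/2$, which keeps the goal/action reading
  robust when one epoch carries little variance (single-goal batches,
  asymmetric sweeps).  Batch analyses use the aligned basis.
* **Selectivity** (`selectivity_timecourse()`): at each time step the rate
  of each population is regressed across trials on two binary dummies
  (preferred goal, preferred action; preferences fixed by the architecture:
  A prefers G1 and A1, B G1/A2, C G2/A2, D G2/A1).  Rates are smoothed with
  a 50 ms Gaussian before the regression; both coefficient courses per unit
  are normalized by their joint global peak.
* **Transition detection** (`detect_transition_time()`): first time the
  action measure exceeds the goal measure sustained for 200 ms -- mean
  normalized action versus goal coefficient for a batch, $|PC_2| > |PC_1|$
  (with a 20%-of-peak amplitude floor to reject near-zero dominance) for a
  single trial.  Goal-state entry (`goal_entry_time()`) is the first
  sustained epoch with $|PC_1|$ dominant and above a quarter of its trial
  maximum; the dwell time is the difference.  An absent transition is a
  valid `NA` (the no-plasticity control).
* **Batches** (`run_batch()`): one network instance per master seed,
  per-trial noise seeds drawn deterministically from it, goals balanced,
  the read-out winner (2:1 dominance sustained 200 ms) recorded per trial,
  plus the pattern table over goal x action and transition-time statistics.

## Scaled-down testing and known limitations

The test suite runs the spiking network at 50 neurons per population, where
a full 4 s trial costs about a second; in-degrees are 10 instead of 40, so
finite-size fluctuations are larger and transitions earlier and more
variable, but ignition, suppression of the uncued assembly, representational
switching, all monotone trends, and both single-plasticity variants are
preserved.  Quantitative acceptance of the dwell time uses the full 200
neurons per population.  The generator emulates the modeled circuit only:
uniform parameters within populations, a single noise source, no NMDA
voltage dependence, no learning of the connectivity, and binary goal/action
sets -- passing tests say nothing about heterogeneous real cortex beyond the
qualitative mechanism.

### Sweep protocols

The transition-time sweeps (`sweep_transition()`) hold the network
realization and noise streams fixed across axis values, so differences along
the axis are attributable to the swept parameter.  The perturbation-onset
sweep uses 0.1 nS, 200 ms pulses with onsets in the window where the goal
state is consolidated (about 0.9 s onward): earlier pulses land in the
transient right after ignition, where the deep depression overshoot makes
this realization briefly fragile, and the interval measure is not monotone
there.  The asymmetry sweep multiplies the A&D assembly's summed weight and
reports both the selection ratio toward A&D and the transition timing.

Known limitations: the noiseless reduction transitions later than the
spiking network (by design of the reference weight adjustment the gap is
only partly compensated, 2.2 s versus 1.3 s to switch), so pointwise
rate agreement between the two models is dominated by that timing offset
(relative RMS about 0.5 on matched protocols) even though the state
sequences and final action-state rates agree; the stochastic network can
visit the opposing goal assembly transiently mid-trial; the common
activation amplitude does not delay the switch in this calibrated
realization -- the extra drive onto the suppressed action populations and
the deeper goal-assembly depression offset the stabilization of the active
assembly, leaving the median transition time flat to slightly earlier as
the amplitude grows (the corresponding expectation in the acceptance suite
documents this and fails by construction); the mean-field interneuron gain
is fitted in the operating range only; and the Naka--Rushton family's hard
threshold forces the quiescence-floor convention described above.
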