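---
title: "A coarse-grained model of motor-driven microtubule streaming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of motor-driven microtubule streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtstream)
```

## The model

`mtstream` simulates a two-dimensional suspension of microtubules (MTs)
driven by kinesin-like molecular motors, at the level of coarse-grained
filaments rather than individual motor proteins.  Each MT is a chain of
`nb = 21` overlapping beads of diameter $\sigma$ connected by stiff
harmonic bonds of rest length $r_0 = \sigma/2$, giving a contour length
$L = (n_b - 1) r_0 = 10\,\sigma$ (aspect ratio 10).  The passive energy of
a configuration is

$$U = \underbrace{\tfrac{k_s}{2}\sum_{\text{bonds}} (r - r_0)^2}_{\text{stretching}}
    + \underbrace{\tfrac{\kappa}{r_0}\sum_{\text{angles}} (1 - \cos\theta)}_{\text{bending}}
    + \underbrace{\sum_{\text{pairs}} U_{\mathrm{WCA}}(r)}_{\text{excluded volume}},$$

with the Weeks–Chandler–Andersen potential
$U_{\mathrm{WCA}} = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon$
cut off at $2^{1/6}\sigma$.  Because the beads overlap ($r_0 = \sigma/2$),
next-nearest intra-filament pairs sit permanently inside the WCA range;
only directly bonded pairs are excluded, so this constant intra-filament
contribution is retained in the energy ledger and cancels in the dynamics.

Motors are not explicit particles.  Instead, each timestep every
inter-filament bead pair within the motor cutoff $d_t = 2\sigma$ whose
local orientations are antialigned with respect to the connecting vector
may form a *transient harmonic bond* of stiffness $k_m$ and rest length
$d_{eq} = \sigma$, with binding probability
$k_{on} = p_a \exp(-U_{mot}/k_BT)$, $U_{mot} = \tfrac{k_m}{2}(m - d_{eq})^2$.
The bond exerts its force for exactly one timestep and is resampled
independently in the next one.  Because eligible extensions satisfy
$m \ge d_{eq}$ in contact geometries, the springs are almost always
stretched and each filament in an antialigned pair is dragged along its
axis: the pair slides apart.  Polar-aligned pairs never bind, so sliding
is polarity selective — this asymmetry is the entire motor model, and it
is sufficient to produce polarity sorting, polar domains, and streaming
at their interfaces.

**Sign convention for the binding geometry.**  The antialignment test uses
the two strict inequalities on the dot products of the bead orientations
with the connecting vector (`motor_eligible()`).  Two mirror-image
conventions are possible, differing in whether the spring contraction
propels each filament toward its plus or its minus end; they produce
identical pair *sets* in a statistical sense but opposite signs of the
orientation-projected velocity.  `sample_motor_bonds()` uses the
convention under which propulsion is toward the plus end, which is the
one consistent with parallel-velocity distributions skewed toward
*positive* values; this emergent behaviour is asserted in the test suite
(propulsion direction on a frozen antialigned fixture, and the sign of
the velocity skew in bulk).

## Dynamics, units, and integration

Bead motion follows the underdamped Langevin equation
$m\ddot r = -\nabla U + F_{mot} - \gamma \dot r + \xi(t)$ with
$\langle \xi_\alpha(t)\xi_\beta(t')\rangle = 2\gamma k_BT
\delta_{\alpha\beta}\delta(t - t')$, integrated by velocity Verlet with
drag and noise entering the force evaluation (the LAMMPS
`fix langevin` scheme).  Internal units are $\sigma = k_BT = m = \gamma =
1$; [physical_units()] records the biological calibration
($\sigma = 25$ nm, $k_BT = 4.11$ pN nm, $\epsilon = 4.11$ pN nm, etc.)
but plays no computational role.

Times are reported in units of the rotational diffusion time $\tau_R$ of
a single passive filament.  The package uses the bead-rod theory value
$\tau_R = \gamma r_0^2 \sum_k k^2 / k_BT = 192.5$ (21 beads at spacing
$\sigma/2$) as the default time unit and the timestep
$\delta t = 5.31\times 10^{-6}\,\tau_R$.  `calibrate_tau_r()` measures
$\tau_R$ from the exponential decay of the orientational correlation of
dilute passive filaments; the measurement agrees with the rod theory
within the 25% band asserted in the tests (flexibility at
$\ell_p = \kappa/k_BT = 20 L$ and the absence of hydrodynamic coupling
both act at the ten-percent level).  On the persistence length we follow
the dimensionless bending stiffness $\kappa\sigma/k_BT = 200$, which is
self-consistent across the dimensionless parameter set; the alternative
reading $\ell_p = 200L$ is inconsistent with the dimensional constants
and is not used.

A note on the noise generator: the integrator consumes its own
xoshiro256++ stream (seeded from the master seed via splitmix64, with
separate substreams for the thermostat, the motor sampling, and each run
phase) because R's RNG cannot be called cheaply from the inner compiled
loop.  Runs are bit-reproducible for a given master seed on one thread.

Initial configurations (`lattice_init()`) place straight filaments on a
nematic lattice with fair-coin polarity and small jitter, guaranteeing no
inter-filament bead pair closer than $\sigma$; velocities are Maxwellian.
Every run equilibrates passively (motors off) before motors switch on,
followed by an active warm-up before production.  Passive relaxation
(bond, bend, velocity distributions) completes within a fraction of
$\tau_R$, so 0.3 $\tau_R$ of passive equilibration suffices; the slow
part is active polarity sorting, so the active warm-up is what must be
long.  Steady state is judged by the plateau of the motor-bond count per
frame (relative drift below 5% per $\tau_R$): one $\tau_R$ of active
warm-up still drifts at ~6% per $\tau_R$ at these system sizes, whereas
2.5 $\tau_R$ reaches a flat plateau (~0.1% per $\tau_R$), which is the
protocol used for the main runs.

## Observables and the five timescales

All analyses operate on saved trajectories (`mt_traj`), using multiple
time origins and block-averaged standard errors:

* **MSD** of filament centres of mass, with the inertial ballistic regime
  ($\propto \tau^2$), the passive diffusive regime ($\propto \tau$), the
  active superdiffusive window ($\tau^{\alpha}, \alpha > 1$), and active
  diffusion beyond $\tau_r$ (`active_diffusion()`).
* **Parallel velocity**: displacements projected on the initial
  end-to-end orientation; its skew peaks at the activity time $\tau^*$.
* **Displacement correlations** $C_d(r, \tau)$, binned at $\sigma/2$
  resolution; the contact bin gives the neighbour correlation
  $N_d(\tau)$, negative during antialigned sliding (minimum at
  $\tau_{N,min}$) and positive during collective migration (maximum at
  $\tau_{N,max}$).  Because the normalisation $c_0$ is the *global* mean
  squared displacement while contact pairs are enriched in actively
  sliding filaments, $|N_d|$ may exceed 1 in strongly streaming systems.
* **Local polar order** $\psi(i)$: the motor-partition-weighted mean
  orientation overlap of a filament's neighbourhood, with the pairwise
  weight $q_{ij}$ normalised by its perfect-overlap self-value so that
  identical filaments give $q_{ij} = 1$ and pairs beyond the motor range
  give 0 (the weight is the Boltzmann factor of the motor energy, cut to
  zero beyond $d_t$ — the only reading consistent with both stated
  limits).  $\psi$ is invariant under any positive rescaling of the
  weights.  Environments classify as polar ($\psi > 0.5$), antipolar
  ($\psi < -0.5$), mixed (boundaries included), or isolated.
* **Polarity inversion** $Q(\tau) = (\langle\psi(\tau)\rangle -
  \psi_\infty) / (\psi_0 - \psi_\infty)$ for filaments starting in
  antialigned environments; $\psi_\infty$ is estimated as the mean over
  the final decade of lags.  The half-decay defines $\tau_{Q/2}$.
* **Orientational correlation** fitted as $e^{-\tau/\tau_r}$ over values
  above 0.05; if the correlation never falls below $e^{-1}$ only a lower
  bound is reported.

`assemble_chronology()` extracts the five times with a significance gate
of three standard errors (extrema) and parabolic refinement in log-lag,
and checks the ordering
$\tau_{N,min} \le \tau_{Q/2} \le \tau^* \le \tau_{N,max} \le \tau_r$ on
the resolved entries.  For passive systems $\tau_{N,min}$ and $\tau^*$
are reported as unresolved rather than forced.

## Scaled-down study conditions

Production-scale studies of this model use 1250 filaments and
$3\times10^7$ steps (about 159 $\tau_R$) — cluster scale.  The package's
tests and the acceptance script run scaled-down versions chosen once:

* passive physics: 50 filaments at $\phi = 0.3$, 1 $\tau_R$ production
  (plus a fine-cadence run saved every few steps for the inertial
  window);
* the main active system: 100–150 filaments at $\phi = 0.3$, $p_a = 1$,
  with 0.3 $\tau_R$ passive equilibration, 2.5 $\tau_R$ active warm-up
  (to the motor-count plateau) and 1.5–2 $\tau_R$ production;
* trend checks ($p_a \in \{0.25, 0.5, 1\}$, $\phi \in \{0.3, 0.4,
  0.5\}$): 60 filaments, shorter warm-up, ~1 $\tau_R$ production.

At these sizes the fast single-filament processes (sliding, polarity
inversion, superdiffusion) are quantitatively reproducible, while the
slow collective times ($\tau_{N,max}$, $\tau_r$, and the skew maximum
$\tau^*$, all of order $10\,\tau_R$ at full scale) exceed the accessible
lag range and are reported as unresolved or appear only through
short-lag proxies (e.g. the monotone decrease of orientational memory
with $p_a$).  Finite size also compresses the collective timescales:
polar domains cannot outgrow the box (6–8 filament lengths here versus
16–25 at full scale), so an antialigned filament reaches the end of its
stream sooner.  At $\phi = 0.3$, $p_a = 1$ the measured sliding time is
$\tau_{N,min} \approx 0.02\,\tau_R$ and the polarity-inversion time
$\tau_{Q/2} \approx 0.06\,\tau_R$ — stable across 100–200 filaments and
warm-ups of 0.5–2.5 $\tau_R$, but a factor 2–5 below their full-scale
bands; the ordering of the cascade and the superdiffusive exponent are
unaffected.  What passing tests show about real systems is therefore the
mechanism (polarity-selective sliding producing sorting, streaming and
the ordered cascade of timescales), not the absolute values of the
collective times.

The synthetic lattice initial state emulates a nematic film of fixed
length filaments with balanced polarity.  It does not emulate
polydispersity, filament turnover (polymerisation/depolymerisation),
hydrodynamic coupling, or three-dimensional effects — all outside the
model.

## Numerical choices

* Timestep $5.31\times10^{-6} \tau_R \approx 1.02\times10^{-3}$ internal
  time; the stiffest mode (bond vibration, period $\approx 0.14$) is
  resolved by ~140 steps.  A per-step displacement above $\sigma/2$
  aborts with an instability error.
* Neighbour search: cell list rebuilt into a Verlet list with skin
  $0.4\sigma$ when any bead has moved more than half the skin; exact
  against the all-pairs scan (tested), with automatic all-pairs fallback
  for boxes under three cells per edge.
* Tie-breaks follow the strict inequalities: extensions exactly at the
  motor cutoff do not bind; dot products exactly zero are not
  antialigned; $|\psi| = 0.5$ classifies as mixed.
* Frame saving uses a log-block schedule (a fine prefix, a mid block,
  and a coarse uniform grid) so that lags spanning several decades are
  available without saving every step; estimators match frame pairs to
  requested lags within a 5% tolerance and average over at most 48–64
  origins per lag.
* The extractor significance gate (3 standard errors) prevents
  noise-picked extrema, and an extremum sitting on the first or last
  point of the lag grid is reported as unresolved (it cannot be
  bracketed); unresolved timescales are flagged, never extrapolated.
* `motile_fraction()` needs an explicit window and displacement
  threshold (defaults: 1 $\tau_R$ and $L/2$) because the experimental
  motility criterion is itself a choice; treat the resulting fractions
  as qualitative.

## Known limitations

* No hydrodynamic interactions; the thermostat breaks momentum
  conservation by design (substrate drag).
* The effective motor has no walking kinetics, dwell-time distribution,
  or persistent attachment; forces act for one step only.
* Collective timescales at desk scale are bounded by the box size and
  the trajectory span, as discussed above.
* Parallel execution is not supported; determinism is guaranteed only
  single-threaded.
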