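---
title: "Computing polymer desorption rates by forward flux sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing polymer desorption rates by forward flux sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single homopolymer adsorbed to an attractive flat wall desorbs at a rate
that can be astronomically small: if each of the $N$ monomers binds with a
free energy that is an appreciable fraction of $k_BT$, the chain as a whole
is bound by $O(N k_BT)$ and a direct simulation will essentially never show
a desorption event. `ffsdesorb` computes such rates with forward flux
sampling (FFS, also known as multilevel splitting): the improbable
transition from the adsorbed basin A to the desorbed basin B is decomposed
into a measurable base flux across an initial interface times a product of
conditional advancement probabilities across intermediate interfaces,

$$ r_{A\to B} \;=\; r_{A\to\lambda_0} \prod_{i=0}^{n-1}
   P(\lambda_i\!\to\!\lambda_{i+1}) \; P(\lambda_n\!\to\! B). $$

Each factor is order $10^{-1}$ and cheap to estimate, while the product can
easily be $10^{-10}$ or smaller.

## Chain models and potentials

The chain is a coarse-grained bead–spring model in kJ/mol, nm, ps, g/mol
units ($k_B = 0.0083144626$ kJ/mol/K; in this unit system $F/m$ is directly
an acceleration in nm/ps² and $\tfrac12 m v^2$ is in kJ/mol). The potential
is

$$ V = \sum_{i\neq j} V_{LJ}(r_{ij})
     + \sum_i V_W(z_i)
     + \sum_i k_b (r_{i,i+1}-l_b)^2
     + \sum_i k_A (\theta_i-\theta_A)^2
     + \sum_i k_D (r_{i,i+3}-r_D)^2, $$

with all harmonic constants multiplying the plain square (no factor ½).
Preset models: `FJC` (freely jointed), `FRC` (adds bending,
$k_A = 2000$ kJ/mol/rad² at $\theta_A = 111.58^\circ$), `+EV`
(12-6 Lennard-Jones between beads $|i-j|\ge 2$, $\sigma_{PP}=0.43$ nm,
$\epsilon_{PP}=0.2$ kJ/mol, cut at $2.5\sigma_{PP}$ and shifted), `+T`
(1–4 distance springs, $k_D = 60$ kJ/mol/nm² at $r_D = 0.6$ nm). Shared
constants: $l_b = 0.33$ nm, $k_b = 16000$ kJ/mol/nm², bead mass 45 g/mol,
$\sigma_{PW} = 0.47$ nm. The bending angle is taken as 111.58° (the more
precise of the two printed values for these models) and $k_A$ in
kJ/mol/rad².

The wall is the Steele 10-4-3 potential

$$ V_W(z) = 2\pi\epsilon_{PW}\Big[\tfrac25 (\sigma/z)^{10} - (\sigma/z)^4
  - \frac{\sqrt2\,\sigma^3}{3\,(z + 0.61\,\sigma/\sqrt2)^3}\Big], $$

the conventional form with interlayer spacing $\Delta = \sigma/\sqrt2$.
Note that $V_W(2\sigma) \approx -0.59\,\epsilon_{PW}$ — small relative to
the well depth ($\approx -4.4\,\epsilon_{PW}$ at $z^* \approx 0.46$ nm) but
not negligible in absolute terms; the mean-field average below therefore
integrates over the full $[0, 2\sigma]$ layer.

The **reaction coordinate** is the contact number
$C = \sum_i s(z_i)$ with the rational switch
$s(z) = \big(1 - x^6\big)/\big(1 - x^{14}\big)$, $x = (z-d_0)/r_0$,
$d_0 = 0.35$ nm, $r_0 = 0.7$ nm, clamped to 1 for $z \le d_0$. The
removable singularity at $x=1$ evaluates to $6/14$; the far tail decays as
$x^{-8}$. $C$ decreases from $\approx N$ to 0 as the chain desorbs; basin B
is $C < 10^{-5}$.

The per-monomer binding strength entering the strong-adsorption scaling is
the Boltzmann-weighted mean wall energy over the near-wall layer,

$$ V_{MF} = -\frac{1}{Z}\int_0^{2\sigma} V_W(z)\, e^{-V_W(z)/k_BT}\,dz,
   \qquad Z = \int_0^{2\sigma} e^{-V_W(z)/k_BT}\,dz, $$

taken positive for attraction and computed by adaptive quadrature
(`stats::integrate`), treating the integrand as zero where the Boltzmann
factor underflows near the hard core.

## Langevin dynamics and the time step

Dynamics follow $m\ddot x = -\nabla V - (m/t_{damp})\dot x + R$ with
$T = 300$ K and $t_{damp} = 0.25$ ps, integrated by velocity Verlet with
impulsive friction and noise: the friction is evaluated at the half-step
velocity (the convention of the major MD engines), and the random force has
per-component variance $2 m k_BT /(t_{damp}\Delta t)$ per step. Two exact
identities of this scheme are worth knowing (both are verified in the test
suite):

* the **full-step kinetic energy** averages exactly $\tfrac32 k_BT$ per
  bead at any stable $\Delta t$, and
* the **free-particle diffusivity** is exactly $D_1 = k_BT\,t_{damp}/m$,
  independent of $\Delta t$ — with the defaults,
  $D_1 = 1.39\times10^{-4}$ cm²/s, and a free chain has $D = D_1/N$ (Rouse
  behaviour: the centre of mass feels the summed friction of its beads and,
  because all conservative forces are internal, performs exact free Langevin
  motion regardless of configuration).

Positions of *stiff* modes, as with any Verlet-family integrator, sample an
effective temperature inflated by $1/(1-(\omega\Delta t/2)^2)$; for the
bond mode at the default step this affects only the ±0.01 nm bond-length
jitter and none of the conformational observables.

**Choice of $\Delta t = 0.03$ ps.** The stiffest phonon of the discrete
chain (the zone-edge bond mode) has $\omega_{max} = 2\sqrt{2k_b/m} = 53.3$
rad/ps. Linear stability of the scheme requires
$\omega_{max}\Delta t < \sqrt{4 - 2\Delta t/t_{damp}}$; a 0.04 ps step
gives $\omega_{max}\Delta t = 2.13$, *outside* the stable window (we
verified numerically that an interior chain then blows up within a few
hundred steps, while a dimer, whose only mode has $\omega\Delta t = 1.51$,
survives). The package therefore defaults to 0.03 ps
($\omega_{max}\Delta t = 1.6$, a conventional safety margin), keeping every
model parameter untouched. Because $D$ and the thermostat identities above
are step-size independent, and because desorption kinetics are insensitive
to the stiff-bond frequency (halving $k_b$ leaves rates unchanged within
error bars, which we also spot-check), this choice affects cost, not
physics. `check_stability()` warns whenever a model/step pair leaves the
window.

**Noise streams.** The C++ core runs on a counter-style RNG
(xoshiro256++ seeded through splitmix64 from a `(seed, stream)` pair, with
ziggurat normals). Every trial, replica and basin run receives its own
stream, so FFS branches are statistically independent, cloned snapshots
keep their stored velocities but get fresh noise (no momentum resampling is
needed in the overdamped regime), and any trajectory can be replayed
bitwise — the base-rate step exploits this to harvest crossing states in a
second pass. All R-level sampling (trial allocation, pilot selection)
derives from the same master seed, so a whole FFS run is reproducible from
one integer.

## Preparing basin A

1. **Coil generation** builds bonds of length $l_b$ with random torsional
   placement (uniform sphere for FJC, fixed bending angle with uniform
   azimuth for FRC); with excluded volume, placements closer than
   $0.8\sigma_{PP}$ to a non-adjacent bead are redrawn, with whole-chain
   restarts if needed. This grown ensemble is exactly the ideal-chain
   ensemble for FJC and approximately the self-avoiding one for +EV.
2. **Equilibration** runs free-space dynamics, measures the end-to-end
   autocorrelation time $\tau_{ends}$ (exponential fit over the window
   where the normalized autocorrelation exceeds $1/e$; the run length is
   sized from the analytic Rouse-time estimate
   $\zeta N^2 l_b^2/(3\pi^2 k_BT)$), then emits snapshots every
   $2\tau_{ends}$.
3. **Adsorption** translates a sample so its lowest bead sits at
   $z = 0.7$ nm, evolves it with the wall on until the COM has drifted
   12 nm away, 90% of beads are adsorbed (operationalized as
   $C \ge 0.9N$ — the contact number is the model's only adsorption
   measure), or $100N$ ps have elapsed; it is accepted as a basin-A state
   if $C \ge \min(10, 0.1N)$, with one retry of another $100N$ ps for
   near-misses ("pre-initialization time"). COM distance is measured from
   the wall plane $z = 0$.

## The FFS engine

**Interfaces.** After running every basin state for $t_{rate}$, the engine
assigns

$$ \lambda_0 = \tfrac12\big(\min_i \langle C\rangle_i +
   \operatorname{median}_i C_{i,\min}\big), \qquad
   \lambda_A = \tfrac12\big(\lambda_0 + \min_i\langle C\rangle_i\big), $$

so $\lambda_A$ marks the outer edge of basin A and the
$\lambda_A$–$\lambda_0$ gap suppresses correlated re-crossings. Crossings
of $\lambda_0$ are counted only when *armed* by a prior downward crossing
of $\lambda_A$; re-arming requires returning above $\lambda_A$. Time spent
in B ($C < 10^{-5}$) and in the B→A transit (until $C$ first re-exceeds
$\lambda_A$) is excluded from the rate denominator. If any run fails to
cross $\lambda_0$, $t_{rate}$ doubles for all runs and the procedure
repeats; the same doubling responds to degenerate interface statistics
($\lambda_A \le \lambda_0$), which occur when runs are too short to
characterize a shallow basin. Two conventions adopted here: per-run
$\langle C\rangle$ and $C_{\min}$ are accumulated only up to a run's first
spontaneous entry into B (after desorbing, the trajectory is no longer
basin-A data), and a run that begins below $\lambda_A$ counts as already
armed. An alternative base-rate estimator (crossings of $\lambda_1$ with
history traceable to $\lambda_0$) is available as `alt_base_rate()` for
cross-checking; the two definitions in circulation are close but not
identical, and the package reports rather than resolves the difference.

**Adaptive levels.** From the current level's snapshots, 100 pilot trials
run until they return to $\lambda_A$ or enter B; the next interface is the
10th percentile of their contact minima — the lower, order-statistic
percentile (`quantile(type = 1)`), a convention we fix because "10th
percentile" alone is ambiguous — floored at $\lambda_B$. Once ≥10% of
pilot minima reach B, the next level *is* B. Production then runs at least
1000 trials under **fixed selection**: each snapshot gets
$\lfloor n/S\rfloor$ trials, the remainder assigned to distinct snapshots
at random — unlike random selection, which leaves a fraction
$(1-1/S)^n$ of snapshots untried and amplifies genetic drift. A trial
succeeds when $C$ first drops below the next interface; the state at that
first touch becomes a next-level snapshot with its parentage recorded.
Pilot trials are discarded from the production estimate. Trials that
exhaust the time cap count as failures and are reported.

**Uncertainties.** Snapshots at a level that share an ancestor $n$ levels
back form an $n$th-order descendant group. A Fisher-type intraclass
correlation $r_i^n$ over the per-snapshot advancement probabilities
$p_{i,j}$, computed around the ancestry-corrected mean (each group's mean
contributes once), identifies the smallest order $L$ with
$r_i^L \le 1/e$; the level's standard error is then the SEM over the
order-$L$ group means. A conservative variant groups by level-0 founders
(any common ancestor ⇒ correlated). Conventions for edge cases: zero
variance across snapshots gives $r = 0$ with a degeneracy flag (and zero
SEM); $|r| > 1$ can occur for tiny samples and is reported unclipped with
the order search proceeding as defined; a single surviving group yields a
flagged `NA` rather than a number. The base rate contributes a Poisson
relative variance $1/k$ on $k$ counted crossings. The 95% interval
propagates in log space:
$\operatorname{var}\ln r = 1/k + \sum_i (\sigma_i/\hat p_i)^2$, giving
$r\,e^{\pm1.96\sqrt{\cdot}}$ for both error flavours.

## Reference estimators

`brute_force_mfpt()` evolves adsorbed states until $C < 10^{-5}$ and
summarizes first-passage times assuming exponential waiting
(Gamma/χ² interval on the mean); it shares the basin bookkeeping with the
FFS engine so the two estimators are comparable by construction. A 1D
quartic double well $V(x) = h(x^2-1)^2$ with order parameter $-x$ (so that
"forward" decreases the order parameter, matching the contact-number
convention) drives the *same* engine code through a second propagator; FFS
vs brute-force agreement there, and against the high-friction Kramers rate
$\frac{\omega_a\omega_b}{2\pi\gamma}e^{-h/k_BT}$, is the package's primary
self-validation.

## Scaling analyses

`radius_of_gyration()`, `fit_power_law()` (log–log least squares) and
`dimensionless_tdes()` ($t_{des} D/R_g^2$) feed three analyses:

* **Flory exponents**: $R_g \propto N^\nu$ with $\nu \approx 0.5$ for
  ideal chains and $\approx 0.6$ with excluded volume;
* **strong-adsorption scaling**: $\ln(t_{des}D/R_g^2)$ against
  $N V_{MF}/k_BT$, whose slope rises toward (but stays below) 1 as
  $\epsilon_{PW}$ grows; $V_{MF}$ is always computed from the wall
  parameters, never fitted;
* **time conversion**: simulated (Rouse) chains have $D \propto N^{-1}$
  against the experimental $N^{-0.589}$, so simulation-to-experiment time
  factors scale as $N^{-0.411}$, anchored at $N = 50$ by the measured
  $D_{sim}$ over the 99 µm²/s experimental reference. The exponent 0.411
  (rather than the rounded 0.4) is used, matching the anchor values at
  $N = 1$ and $N = 10^3$.

## What the desk-scale experiments do and do not show

The test suite and the acceptance script run the whole pipeline at sizes a
single CPU handles in minutes: chains up to $N = 200$ for conformational
statistics, brute-force desorption at $\epsilon_{PW} = 0.2$ kJ/mol for
$N \le 100$ with 20 events per condition, FFS–brute-force cross-checks at
$N = 25$, and the slope-ordering property at
$\epsilon_{PW} \in \{0.4, 0.6\}$, $N \in \{16, 32\}$. These sizes are the
package's validation choices: large enough for the scaling exponents and
method agreement to be resolved at their stated tolerances, small enough
to rerun routinely. They demonstrate correctness of the machinery and of
the weak-adsorption (diffusion-controlled) regime; they do not reproduce
production-scale strong-adsorption sweeps (monomer attractions of several
kJ/mol and desorption times spanning tens of orders of magnitude), which
require cluster-scale computing. Free-chain conformational ensembles are
sampled by direct construction for ideal chains (exact) and by pivot
Monte Carlo (`pivot_sample()`) for interacting ones: per-sample
Rouse-time dynamics would cost $O(N^2)$ relaxation times each, while
pivot moves decorrelate global observables within a few accepted
rotations. The pivot sampler is validated against the exact ideal-chain
$R_g^2 = l_b^2(N^2-1)/6N$ and against long Langevin trajectories at
$N = 25$, where that comparison is affordable. Basin-A preparation, in
contrast, always uses plain dynamics — near the wall there is no valid
pivot move set, and the kinetics themselves are the object of study.

One measured caveat: the waiting times between counted $\lambda_0$
crossings are exponential for a cleanly metastable system (the double
well passes a KS check comfortably), but for weakly adsorbed chains they
remain over-dispersed — bursts of crossings occur while the chain
lingers at the basin edge, because the slow variable (how much of the
chain is attached) relaxes more slowly than the $\lambda_A$–$\lambda_0$
re-arming gap. This does not bias the base rate, which is a net-flux
count per unit eligible time, and the FFS–brute-force agreement is
verified directly on the polymer; it does mean the base-rate Poisson
error is optimistic at very weak adsorption.

Synthetic-data caveats: the model has no hydrodynamic interactions (free
draining, so $D \propto 1/N$ exactly), no explicit solvent, no
electrostatics, a perfectly flat homogeneous wall, and a somewhat
arbitrary desorbed-state criterion $C < 10^{-5}$ — trends in $N$ and
$\epsilon_{PW}$ are robust to that choice but absolute times depend on it
weakly (longer chains must drift farther before all contacts decay).

## Known limitations

* The printed stiff-bond/step combination is integrator-unstable (see the
  time-step section); we run at 0.03 ps instead.
* Basin-A samples inherit the adsorption protocol's stopping rules; at
  very weak attraction the "90% adsorbed" stop biases starting states
  toward maximal adsorption. The first-passage times relax this within a
  small fraction of $t_{des}$.
* At weak attraction the adaptive machinery may place only one or two
  interfaces between $\lambda_0$ and B — FFS then degenerates gracefully
  toward direct simulation, and the brute-force estimator is the cheaper
  choice.
* The intraclass-correlation error analysis assumes enough snapshots per
  level for group statistics; levels that collapse to a single lineage
  only carry the conservative flag, not a number.
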