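---
title: "Shock-compression dynamics and reactive trajectory analysis with shockmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-compression dynamics and reactive trajectory analysis with shockmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockmd)
```

## The problem

When an iron-rich impactor strikes an ocean engulfing atmospheric N₂, the
shock front compresses and heats the mixture within picoseconds; water
dehydrogenates on the oxidising iron surface, the liberated hydrogen
reduces adsorbed dinitrogen, and ammonia forms. The first-principles
simulations behind this picture are far beyond desk scale, but everything
*around* the electronic structure — the shock-dynamics bookkeeping, the
reactive bond analysis, the transport and rate estimators — is classical
and testable. `shockmd` implements that machinery in full, with seeded
synthetic generators standing in for ab-initio trajectories, so every
analyzer can be validated against fixtures whose ground truth is known by
construction.

Internal units are Å, fs, amu, eV throughout; interfaces use GPa, km/s,
g/cm³, cm²/s and K, with all conversions centralised (`to_si`,
`shock_constants`). Boltzmann and Planck constants are CODATA 2018.

## Shock dynamics: the MSST cell

A steady planar shock travelling at speed $V_s$ connects the unshocked
state $(P_0, V_0)$ to compressed states on the Rayleigh line
$P = P_0 + \rho_0 V_s^2 (1 - V/V_0)$, with particle velocity
$U_p = V_s (1 - V/V_0)$ by mass conservation and energy jump
$\Delta E = \tfrac12 (P + P_0)(v_0 - v)$. The multi-scale shock technique
(MSST) reproduces such states with a small periodic cell by making the
volume a dynamical variable. The engine integrates, by velocity Verlet
with operator-split cell updates,

$$\ddot V = \frac{M}{Q}\left(P_{xx} - P_0 - \rho_0 V_s^2
  \left(1 - \frac{V}{V_0}\right)\right),$$

the stationarity condition of the extended Lagrangian whose conserved
energy is

$$E = \mathrm{KE} + \Phi + \frac{Q}{2M}\dot V^2 + P_0 (V - V_0)
  - \frac{M V_s^2}{2}\left(1 - \frac{V}{V_0}\right)^2 .$$

Only the $x$ cell edge strains (uniaxial shock); atom velocities acquire
the scaled-coordinate coupling $\dot v_x = F_x/m - (\dot V/V)\,v_x$.

Numerical choices worth knowing:

* **Time step** defaults to 0.242 fs (10 a.u.). On the 64-atom
  Lennard-Jones fixture the extended energy drifts below
  $10^{-4}$ eV/atom/ps and the NVE limit below $10^{-5}$ eV/atom/ps.
* **Cell mass $Q$** (units amu²/Å⁴) defaults to
  $(M V_s \tau_{\mathrm{cell}} / 2\pi V_0)^2$ with
  $\tau_{\mathrm{cell}} = 100\,dt$, which puts the small-oscillation
  period of the cell near 100 steps — slow enough for the atoms to follow
  adiabatically, fast enough to converge in a few thousand steps.
* **Branch selection.** The unshocked state is an *unstable* stationary
  point: for a supersonic $V_s$ both compression and expansion run away.
  The engine seeds the compressive branch by converting a fraction
  `tscale` (default 1%) of the initial atomic kinetic energy into an
  inward cell velocity, and clamps any expansion beyond $V_0$
  (rarefaction is explicitly out of scope). `tscale = 0` preserves the
  exact unshocked fixed point.
* **Stationarity.** Conservative MSST oscillates around the shocked
  state; an optional artificial-viscosity time constant `cell_damp`
  (finite values dissipate cell kinetic energy only) settles it onto the
  Rayleigh line, where the virial $P_{xx}$ and the Rayleigh expression —
  two independently computed quantities — agree to well under 2%.
* The pair cutoff must stay below half the smallest cell edge
  (minimum-image convention); the integrator enforces this, which matters
  as the $x$ edge shrinks under compression.

The Nosé–Hoover thermostat is a single chain with coupling period
$50\,dt$ and the Martyna-style symmetric half-step update; the target is
the kinetic temperature over $3N-3$ degrees of freedom (centre-of-mass
motion removed; one fewer with a distance constraint).

## Constrained dynamics and the mean force

`constrained_window()` holds one interatomic distance fixed by RATTLE
(position residual $<10^{-8}$ Å every step, velocity projection after the
force half-kick) and records the multiplier $\lambda$ each step from the
SHAKE position correction. The sign convention — fixed here because the
blue-moon literature varies — is that $\lambda > 0$ when the potential
pushes the pair apart, so that

$$\Delta F(r) = \int_r^{r_0} \langle\lambda\rangle\, dr'$$

(trapezoidal rule along the *decreasing* coordinate, as the tables are
produced) yields a positive barrier between the equilibrium distance
$r_0$ (where $\langle\lambda\rangle = 0$) and the product distance $r_d$.
On a harmonic dimer at $T \to 0$ the recorded multiplier equals $k_0\delta$
exactly; at finite temperature it carries the expected $2k_BT/r$
entropic term, which the tests verify. The first 20% of each window is
discarded as equilibration (the windows are short, 1 ps, and the
integrand is stiff at the start).

Rates then follow from transition-state theory,
$k = (k_B T/h)\,e^{-\Delta F^\ddagger/k_B T}$: a 0.09 eV barrier gives
26.6 ps⁻¹ at 2100 K and 10.5 ps⁻¹ at 1200 K. Applying a barrier computed
at 300 K to shocked temperatures is an approximation inherited from the
study design; the calculator takes barrier and temperature independently
so the assumption is explicit.

## Reactive bond analysis

A bond exists between two atoms once they have remained inside their
pair-type cutoff *continuously* for the lifetime (default 2.42 fs, i.e.
$L = 10$ frames at $dt = 0.242$ fs; the lifetime must be an integer
number of frames). The bond is stamped at the frame completing the
window and drops at the first excursion. Cutoffs default to the values
read off the first minima of the shocked system's partial radial
distribution functions: H–O 1.25, O–Fe 1.50, H–N 2.00, H–Fe 2.50 Å. The
H–N cutoff deliberately captures hydrogen bonds as well as covalent
bonds, as the counting it mirrors does. `first_minimum()` implements the
cutoff construction (5-bin moving-average smoothing, first local minimum
after the first peak).

Speciation needs a full covalent table, so `full_bond_criteria()` adds
N–N 1.8, H–H 1.0 and N–Fe 2.3 Å (O–H is the same unordered pair as H–O);
all values are overridable and pairs absent from the table are skipped
with a once-per-session warning. Molecules are connected components of
the bond graph; formulas are element counts. NH₃ is a component of
exactly one N and three H — which also encodes "not bonded to Fe", since
a bonded Fe would join the component. Charge states cannot be assigned
from geometry, so the census reports neutral formulas and protonation
topology only (NH₄ stands for the ammonium topology). Formation events
are tracked per nitrogen atom: one event the first time that atom's
component attains the target formula, and the cumulative count never
decrements — protonation of NH₃ to NH₄ leaves it unchanged.

Mulliken bookkeeping is the arithmetic $Q_i(t) = Z^0_i - Z_i(t)$ on
user-supplied gross populations (default valence counts N 5, O 6, H 1,
Fe 8 for the corresponding projector set); computing populations from
wavefunctions is out of scope.

## Transport

`msd()` averages squared displacements over time origins (default stride
10 frames) on unwrapped coordinates — trajectories carry an `unwrapped`
slot precisely because wrapping destroys displacement statistics. The
default maximum lag is 25% of the trajectory and `diffusion_coefficient`
fits `slope/6` over the 20–80% lag window, inside the diffusive regime
for the fixtures used. On Brownian fixtures the estimator is unbiased;
its error shrinks with trajectory length (verified at two lengths).

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline needs, bit-reproducibly
under a seed:

* `build_initial_system()` — the 182-atom Fe₃₆/16 N₂/38 H₂O supercell
  (29.72 × 8.580 × 8.580 Å): a 2×3×3 bcc slab (a = 2.86 Å) centred in
  $x$, molecular sites on a jittered grid in the water slabs, 16 N₂
  substituted at random sites, orientations rejection-sampled to keep
  every interatomic distance ≥ 0.7 Å. It approximates the topology of an
  optimized configuration, not its coordinates.
* `script_reactive_trajectory()` — chemistry by geometry: events
  (proton transfer, N–N scission, adsorption, protonation) reposition
  atoms at prescribed frames over a static background with Gaussian
  jitter (default 0.05 Å/atom/frame). Bonded distances are engineered at
  least six jitter standard deviations inside their cutoffs, so a bonded
  pair essentially never flickers out; spurious bond *creation* is
  suppressed by the lifetime filter itself (10 consecutive in-cutoff
  frames of independent noise). `ammonia_event_fixture()` schedules the
  third N–H arrival $L-1$ frames before each target time so the bond
  completes its lifetime exactly at the requested frame;
  `bond_inventory_fixture()` realises an exact engineered bond inventory
  (43 H–O, 47 O–Fe, 24 H–N, 18 H–Fe) from the reference composition.
* `brownian_trajectory()` — independent Gaussian steps of variance
  $2D\,dt$ per axis; `shock_profile_fixture()` — a sigmoidal
  $V/V_0(t)$ with P and $U_p$ derived through the jump relations, so
  every row satisfies them identically.

What passing tests on these fixtures shows: the analyzers implement
their definitions exactly (lifetime semantics, graph speciation,
cumulative counting, MSD/TI/TST/jump arithmetic) and the MD engine obeys
its conservation laws and statistical contracts. What they do not show:
anything about real reactive matter — there is no electronic structure,
no emergent chemistry, no water structure, and the pair potentials are
generic. The package is a pipeline validator and teaching instrument,
not a substitute for ab-initio dynamics.

## Problem sizes

The shipped tests use a 32–64 atom Lennard-Jones crystal (nearest-
neighbour cutoff 3.2 Å, ε = 0.1 eV, σ = 2.2 Å, iron mass) for the
dynamics contracts — large enough for meaningful statistics, small
enough that the full suite runs in about a minute — and full-length 4 ps,
0.242 fs fixtures (16 530 frames, 182 atoms) for the analyzer checks.
Diffusion recovery uses 20 replicates of 36 walkers over 4 ps.

## Known limitations

* Only orthorhombic cells are integrated (triclinic geometry is supported
  for analysis); the shock is uniaxial along $x$.
* One distance constraint per run; no constraint networks.
* The MSST velocity coupling uses the scaled-coordinate form with the
  particle velocity defined as $h\dot q$; alternative conventions differ
  at $O(\dot V/V)$.
* Bond detection is $O(\text{pairs} \times \text{frames})$ in plain R;
  fine for $10^4$ frames × $10^4$ candidate pairs, not for production
  trajectories orders of magnitude larger.
* The NH₄ flag is topological; true charge assignment would need the
  electronic populations the package deliberately treats as input data.
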