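---
title: "Measuring and correcting the Galvani offset potential in constant-pH simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and correcting the Galvani offset potential in constant-pH simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galvanic)
```

## The problem

Periodic molecular simulations almost universally treat long-range
electrostatics with Ewald summation under *tinfoil* boundary conditions: the
k = 0 Fourier component of the potential is dropped, which is equivalent to
embedding the periodic system in a perfect conductor with a uniform
neutralizing background.  A direct consequence is that the electrostatic
potential averaged over the simulation cell is pinned to zero at all times.
The potential of any particular *region* of the cell is therefore not an
absolute quantity: the mean phase potentials of the different regions must
counterbalance one another.  If the water phase occupies a volume fraction
$f_w$ and the remainder (protein, membrane, vacuum) a fraction
$f_r = 1 - f_w$, then

$$ f_w \langle\phi_w\rangle + f_r \langle\phi_r\rangle = 0
   \quad\Longrightarrow\quad
   \langle\phi_w\rangle \approx -f_r\,\Phi_{wr}, $$

where $\Phi_{wr}$ is the mean interfacial Galvani potential between water
and the non-water remainder.  In a box that is mostly water,
$\langle\phi_w\rangle \approx 0$ and charging free energies computed there
implicitly define the reference state.  In a membrane–protein box, where
$f_w$ can be 0.65–0.9, the bulk water sits at a substantially negative
Galvani potential, of order $-100$ mV.

This matters for constant-pH simulations because the acceptance of a
protonation attempt depends on the work of charging a site by
$\Delta Q = \pm e$.  A spurious bulk potential $\phi$ shifts every apparent
pKa by $e\,\phi / (k_B T \ln 10)$ — one pH unit per 59 mV at 298.15 K.  The
remedy implemented here is an *offset correction*: measure the bulk-water
Galvani potential $\langle\phi_w\rangle$, set
$\phi_{\rm offset} = -\langle\phi_w\rangle$, and correct the nonequilibrium
switching work as

$$ W \rightarrow W + \Delta Q_{\rm tot}\,\phi_{\rm offset}, $$

which restores the all-water reference state exactly.

The package implements this whole chain at desk scale: tinfoil Ewald
potential maps, region classification and peak estimation, a toy
constant-pH nonequilibrium MC engine with the work correction, and binless
WHAM titration analysis, together with seeded synthetic fixtures whose
ground truth is known in closed form.

## Potential maps

`compute_potential_grid()` evaluates the reciprocal-space Ewald potential of
Gaussian-smeared charges on a regular lattice, omitting k = 0.  The
structure factor is accumulated exactly (no interpolation onto the grid), so
the map equals the explicit k-sum of `direct_ksum_potential()` to
floating-point accuracy; the tests verify agreement to $10^{-6}$ relative at
every node.  Two modes exist:

* **smoothed** (default): reciprocal sum only.  This is the convention of
  grid-based potential-map tools; the map is the exact potential of the
  smeared charge density.  The default smearing $\beta = 0.25$ Å$^{-1}$
  (Gaussian width 4 Å) is a compromise: wide enough that a 1 Å grid resolves
  the density, narrow enough that plateau regions of bulk phases are
  unaffected.  Plateau values — the quantity the offset analysis needs — are
  independent of $\beta$, because smearing leaves flat regions flat.
* **exact**: adds the complementary `erfc` short-range term over minimum
  images within `rcut`.  This recovers the point-charge potential and is
  independent of $\beta$; the tests confirm smearing-independence to
  $10^{-6}$ and recovery of the rock-salt Madelung constant $-1.747565$
  against an Evjen expanding-cube oracle.

Grid dimensions default to `round(box / 1 Å)` per axis so that per-frame
maps follow fluctuating box dimensions at fixed nominal resolution.
Non-neutral systems are accepted: dropping k = 0 implicitly supplies the
uniform neutralizing background.  Boxes are orthorhombic only.

## Region classification and the bulk-water peak

`build_occupancy()` deposits each atom onto the 3D map of its species
(solvent / protein / membrane) as a periodic normalized Gaussian, 1.0 Å wide
by default, and `classify_cells()` assigns each cell to the species of
highest density.  Exact ties are broken by the fixed priority protein >
membrane > solvent; cells where every density falls below a floor
(default $10^{-3}$ atoms/Å$^3$) are vacuum and are excluded from volume
fractions and histograms.  Condensed-phase frames have essentially no vacuum
cells; synthetic fixtures may legitimately contain empty space.  Ions are
conventionally labeled solvent (a 150 mM salt bath is part of the bulk
phase); species come from input labels, never from chemical perception.

The bulk-water potential is estimated from the *highest peak* of the
solvent-region histogram (1 mV bins by default) rather than from a spatial
mean, because cells near the protein or membrane do not reflect the bulk
phase and would bias a mean.  The mode bin is refined by a three-point
parabolic fit; an exact tie between bins resolves toward the solvent-region
mean.  `galvani_offset()` chains the whole per-frame pipeline and averages
over frames; its result carries $\langle\phi_w\rangle$, $f_w$, and
$\phi_{\rm offset} = -\langle\phi_w\rangle$.

## The charged-slab fixture and its closed form

The analysis needs a periodic system with a *known* interfacial potential
step.  A single pair of oppositely charged plates is not suitable: it
carries a net dipole across the periodic cell, so under tinfoil conditions
the exterior potential is a linear sawtooth and there is no solvent plateau
at all.  `make_capacitor_slab()` therefore builds the simplest system that
does have exact plateaus: a mirror-symmetric slab whose two faces each carry
a dipole layer (a $-\sigma$ sheet on the outside, a $+\sigma$ sheet a
distance $d$ inward, like the leaflets of a bilayer with the negative side
facing water).  The cell then has zero net dipole, the exterior field
vanishes exactly, and

* the interior core sits at $\Delta\phi = 4\pi k_C \sigma d$ above the
  solvent plateau,
* the slab interior averages $\Delta\phi\,(1 - d/T)$ above the solvent for
  slab thickness $T$ (the linear ramps inside the dipole layers count at
  half weight), and
* the zero box average pins the solvent plateau at
  $\langle\phi_w\rangle = -\Delta\phi\,(T - d)/L_z$, i.e. $-f_r$ times the
  mean slab offset — exactly the volume-fraction balance above.

Every generated slab ships this ground truth in its `ground_truth`
attribute, and the tests require the full map–classify–histogram–peak
pipeline to recover it within 2% over $\sigma \in [10^{-4}, 10^{-3}]$
e/Å$^2$ and $d \in [5, 20]$ Å, and to produce $(f_w, \langle\phi_w\rangle)$
points that fall on a straight line through $(1, 0)$ as the box height
grows — the same structure observed when a membrane–protein system is
resolvated at increasing box heights.  Neutral filler lattices (membrane
inside the slab, solvent outside) make the geometry visible to the
classifier without perturbing the potential.  Plate sites carry fractional
charges $\sigma \times$ (lattice spacing)$^2$, which keeps $\sigma$
continuous.

The random-electrolyte fixture deliberately has *no* interfacial dipole, so
its solvent peak must be centered at zero.  One caveat the tests make
explicit: a single static snapshot of a point-charge gas is dominated by a
few long-wavelength potential modes, so its per-frame mode fluctuates by a
large fraction of the potential spread; only the frame-averaged peak is
statistically zero.  Real solvent self-averages much more strongly (many
weak, structured charges and time averaging), which is why single-frame
potential maps of water boxes do show a sharp peak.  This is a known gap
between the fixture and real data: passing tests demonstrate the estimator
is unbiased, not that single frames of real systems behave like single
frames of the fixture.

## The toy constant-pH engine

The nonequilibrium MC constant-pH scheme is Hamiltonian-agnostic, so the
engine exercises it on the simplest model with analytic free energies: each
titratable site is a 1D particle with unprotonated well
$U_u = \tfrac12 k x^2$ and protonated well
$U_p = \tfrac12 k (x-d)^2 + \varepsilon$.  With equal force constants the
configurational integrals cancel and the model-compound free-energy gap is
exactly $\Delta G = \varepsilon$ (verified in the tests against a numerical
thermodynamic-integration oracle).  The extended pH-dependent potential is

$$ U(x, \lambda) = (1-\lambda) U_u(x) + \lambda \left[ U_p(x)
   + \Delta Q\,\phi_{\rm env} - C + k_B T \ln 10\, \mathrm{pH} \right],
   \qquad C = k_B T \ln 10\, \mathrm{p}K_a^{\rm ref} + \Delta G, $$

so that at $\phi_{\rm env} = 0$ the stationary protonated fraction is the
Henderson–Hasselbalch curve with midpoint $\mathrm{p}K_a^{\rm ref}$.  The
imposed $\phi_{\rm env}$ models the artifact: the Galvani potential felt by
the protonated charge.

Each cycle runs a few equilibrium overdamped-Langevin steps, picks a site
uniformly at random, proposes the deterministic flip of its $\lambda$,
drives $\lambda$ linearly over `n_switch` increments (accumulating the work
as energy differences at fixed coordinates), corrects the work by
$\Delta Q_{\rm tot}\,\phi_{\rm offset}$, and accepts with probability
$\min(1, e^{-W_{\rm corr}/k_B T})$.  Rejected attempts restore the
pre-switch state exactly; only $\lambda \in \{0, 1\}$ endpoints are ever
retained.  Because the proposal is symmetric and the switch protocol is
time-reversible, the stationary occupancies match the analytic probability
for any switch length — the tests check `n_switch` of 1, 10 and 100 — and
the work distribution satisfies the Jarzynski identity against the analytic
$\Delta G$.

Numerical choices: Euler–Maruyama integration with `dt = 0.01` and unit
friction (the well relaxation time is $\gamma/k = 0.5$, i.e. 50 steps, so
the discretization drift per step is 2%); default toy parameters
$k = 2$ kcal/mol/Å$^2$, $d = 1$ Å, $\varepsilon = 1$ kcal/mol, chosen so
that switching work, thermal noise and the free-energy gap are all of order
$k_B T$; site occupancies are initialized from the analytic probability at
the run's residual potential so short runs start near stationarity.  The
default protocol — 400 cycles, 200-step switches, 10 equilibrium steps —
mirrors the structure of production constant-pH protocols (hundreds of
cycles, switches much longer than the equilibrium segments) at a size where
a full titration study runs in seconds on one core.  Temperatures default to
298.15 K where printed Nernst-style numbers are checked and 310 K is the
simulation default elsewhere.

## Binless WHAM titration

Runs at conditions $(\mathrm{pH}_i, \phi_i)$ are combined without binning.
Because the condition-dependent part of the extended potential is linear in
the total proton count $n$, the reduced energy of a snapshot under condition
$j$ is simply

$$ u_j(n) = n \ln 10\, \mathrm{pH}_j + n\, \Delta Q\, \phi_j / k_B T, $$

with all condition-independent configurational terms dropped (they cancel in
every WHAM difference).  The per-condition free energies solve the standard
self-consistent equations; `solve_wham()` iterates them in log space
(tolerance $10^{-8}$ on $\max|\Delta f|$, at most $10^5$ iterations, gauge
$f_1 = 0$), collapsing snapshots onto distinct proton counts with
multiplicities, so the arithmetic is immune to overflow for reduced energies
up to several hundred.  Conditions with zero snapshots are appended freely —
that is how `titration_curve()` evaluates the protonated fraction on an
arbitrary pH grid at an arbitrary Galvani potential — and the tests verify
they never perturb the sampled-condition free energies.

`fit_pka()` fits the one-parameter Henderson–Hasselbalch curve
$f(\mathrm{pH}) = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$ by least
squares; a unit Hill coefficient is the correct model for independent sites,
and an optional Hill-exponent fit exists but is off by default.  Curves that
do not span their midpoint are flagged as extrapolated with a warning.
Whether WHAM is run on per-site occupancy vectors or total proton counts is
immaterial for identical independent sites, so the implementation uses total
counts.

## The correction experiment at toy scale

The package's headline check mirrors the membrane-protein experiment in
miniature.  A site with reference pKa 4.0 is placed in an environment at
$\phi_{\rm env} = -178$ mV (the bulk-water potential measured in a compact
membrane–protein box).  Runs *without* correction sample an apparent pKa
near 7.0 — upshifted by $e \times 178\,\mathrm{mV} / (k_B T \ln 10) = 3.0$
units at 298.15 K — while runs with $\phi_{\rm offset} = +178$ mV recover
4.0.  `scripts/acceptance.R` recomputes both numbers from scratch; the test
suite asserts them to ±0.1 pKa units with fixed seeds.  Problem sizes
throughout (400 cycles per pH, five to eight pH values per titration, grids
of $\sim 10^4$–$10^5$ cells, 16–24 fixture frames) were chosen so each
analysis carries enough statistics for those tolerances while a full run of
every check completes in a few minutes on one core.

## Limitations

* The toy engine shares the *acceptance criterion and bookkeeping* of
  production constant-pH codes, not their dynamics: there is no molecular
  system, no solvent reorganization, and acceptance rates are not
  comparable to all-atom values.
* The slab fixture realizes an ideal, laterally uniform dipole layer; real
  membranes have rough, fluctuating interfaces and their interfacial
  potential emerges from molecular multipoles.  Nothing in the package
  attempts to predict $\Phi_{wr}$ for real matter (e.g. the ~$-540$ mV
  water–vacuum value of common water models); it only measures offsets from
  given configurations.
* Only orthorhombic boxes are supported, and potential maps use the plain
  FFT of the exactly accumulated structure factor — there is no
  B-spline/PME interpolation emulation, which is unnecessary for potential
  maps at this scale.
* WHAM uncertainty is assessed by seed replication only; no asymptotic
  covariance estimates are produced, and no inter-site cooperativity models
  are available.
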