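---
title: "Hybrid particle-field MD of surfactant self-assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid particle-field MD of surfactant self-assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The physical problem

`hpfmd` models the self-assembly of a polarity-inverted amphiphile —
an adamantane (apolar) head attached to a triethylene-glycol tail
ending in a hydroxyl group, called ADOH throughout — in two solvents:
water, where it behaves as a conventional micelle former with the
bulky apolar head buried in the core, and cyclohexane, where only
labile, transient clusters form.  The package provides the
coarse-grained simulation engine, the system builder, and the complete
analysis pipeline (clustering, radial distribution functions,
diffusion, CMC estimation, Ornstein–Zernike scattering fits, packing
parameter) needed to study this at desk scale.

# The hybrid particle-field model

## Coarse-grained mapping

Five bead species: `A` (adamantyl C10H15, 135.2 amu), `E` (one
C2H4O glycol repeat, 44.05 amu), `T` (terminal hydroxyl, 17.01 amu),
`C` (one cyclohexane molecule, 84.16 amu) and `W` (four water
molecules, 72.06 amu).  ADOH is the linear chain A–E–E–E–T with four
harmonic bonds.  Masses follow directly from the mapped atoms; they
affect only the time scaling of the dynamics, not equilibrium
structure.

## Interactions

Nonbonded interactions are not pairwise.  Particles are assigned to a
cubic mesh by cloud-in-cell (CIC, trilinear) weights, giving
per-species number densities $\phi_i(\mathbf r)$.  The interaction
energy is the density functional

$$W[\phi] \;=\; \sum_{\text{cells}} \frac{v_{\text{cell}}}{\phi_0}
\left[\tfrac12 \sum_{ij}\tilde\chi_{ij}\,\phi_i\phi_j
+ \frac{\kappa^{-1}}{2}\Big(\sum_i \phi_i - \phi_0\Big)^{\!2}\right],$$

where $\phi_0$ is the total reference density,
$\tilde\chi_{ij}$ (kJ/mol) is the Flory–Huggins-like interaction
matrix, and $\kappa^{-1}$ (kJ/mol) penalizes total-density
fluctuations.  Each particle of species $i$ then feels the external
potential

$$V_i = \frac{\partial W}{\partial \phi_i}
= \frac{1}{\phi_0}\Big[\sum_j \tilde\chi_{ij}\phi_j
+ \kappa^{-1}\Big(\sum_j\phi_j - \phi_0\Big)\Big].$$

The default $\tilde\chi$ matrix (see
`default_adoh_forcefield()`) makes water strongly repel the
adamantane head ($\tilde\chi_{AW} = 33.75$ kJ/mol $\approx 13.5\,k_BT$
at 300 K) while being nearly ideal toward the tail; cyclohexane is
athermal toward the head and mildly repels the tail.  That asymmetry is
the entire thermodynamic driving force for micellization in water and
for its absence in cyclohexane.

## Forces: an energy-consistent gradient

The force on a particle is computed as the *exact* negative gradient
of the discretized $W$ with respect to its position: the derivative of
its CIC weights contracted with its species' potential mesh.  This
amounts to a two-point difference of $V_i$ between the two mesh planes
bracketing the particle, weighted by the transverse CIC weights.  We
chose this over interpolating a node-centered central-difference
gradient because only the exact form makes force and energy mutually
consistent — the package's force tests verify agreement with central
finite differences of the total discretized energy to better than
$10^{-4}$ relative, which pins the implementation unambiguously.
Bonded forces are plain harmonic bonds under the minimum image
convention.

## Mesh resolution

The mesh cell edge defaults to about 0.4 nm
(`mesh_cells = round(box_edge / 0.4)`), the coarse-grained bead
diameter scale.  This is a consequential numerical choice bounded on
both sides.  With cells much coarser than a bead (1 nm, say) the
compressibility penalty cannot "see" two beads sharing the same
sub-cell volume: distinct molecules can then superimpose completely
— at exact superposition the field exerts identical forces on both,
so nothing separates them — and the surfactant–surfactant pair
correlation develops an unphysical spike at $r \to 0$ instead of a
first maximum at contact distance.  At 0.4 nm cells two superimposed
beads raise the local density enough to cost several $k_BT$ through
$\kappa^{-1}$, restoring the short-range correlation hole.  Pushing
much finer (0.33 nm and below) overshoots: cells then hold well under
one particle on average, the instantaneous fields degenerate into
shot noise, and the mean-field demixing forces wash out, visibly
weakening aggregation.  0.4 nm sits between the two failure modes;
fields are refreshed every 20 steps and forces averaged over the CIC
support, which keeps the remaining cell-scale noise tolerable.

## Electrostatics

For cyclohexane systems the tail beads carry alternating partial
charges $(+0.4, -0.4, +0.4, -0.4)\,e$ on E1, E2, E3, T — alternation
plus molecular neutrality fixes the placement, since only the
magnitude and alternation are physically prescribed — mimicking the
weak tail–tail dipolar attraction that drives transient dimerization
in the apolar solvent.  The Poisson equation is solved spectrally on
the same mesh (CIC charge spreading, continuum Green's function with
relative dielectric constant $\epsilon_r = 5$, zero-mean potential,
$ik$ differentiation with the Nyquist derivative zeroed), and the
field is interpolated back to the particles.  This is a smooth
mesh-scale electrostatics, validated against the analytic Coulomb
force in the far field (pair at 3 nm, 0.5 nm cells, within 5%); it
makes no attempt to resolve sub-cell Coulomb structure.

## Integration and thermostat

Velocity-Verlet with $\Delta t = 0.03$ ps.  The density field, the
potentials $V_i$ and (when active) the electrostatic field are
recomputed every 20 steps and frozen in between — the
quasi-instantaneous field approximation standard in particle-field
MD.  Temperature is held at 300 K by an Andersen thermostat: each
step, each particle's velocity is redrawn from the Maxwell–Boltzmann
distribution with probability $\nu\,\Delta t = 0.21$
($\nu = 7\,\mathrm{ps}^{-1}$).  With interactions and thermostat
switched off the integrator is symplectic (energy drift below 0.1%
over $10^4$ steps in the chain-fluid test).  All units are nm, ps,
amu, K, kJ/mol and elementary charges, with
$k_B = 0.0083145$ kJ/mol/K; conversions (e.g. diffusion to
$10^{-5}\,\mathrm{cm^2/s}$) happen only at reporting boundaries.

# System building

`molecule_count(c, L)` rounds $c N_A L^3$ to the nearest integer and
reproduces the published simulation compositions exactly (330
amphiphiles at 200 mM in 14 nm; 661 at 50 mM in 28 nm; 13 at 1 mM,
where 13.22 rounds down).  Solvent fills the remaining volume at bulk
liquid density — $\rho_W = 33.33$ molecules/nm³ mapped 4:1 and
$\rho_C = 5.574$ molecules/nm³ (liquid cyclohexane at 0.779 g/mL)
mapped 1:1 — after subtracting a displaced volume of 0.89 nm³ per
amphiphile; these defaults land within 1% of every published solvent
count.  Molecules are placed by random sequential insertion as freely
jointed chains with a 0.25 nm minimum inter-bead distance (cell-list
accelerated), and velocities are Maxwell–Boltzmann at the target
temperature with the center-of-mass drift removed.

# Synthetic fixtures and what they prove

Two generators carry their own ground truth so every analysis stage is
testable without the engine:

* `make_planted_clusters()` builds a surfactant-only configuration
  whose cluster partition is known by construction (clusters well
  separated on a grid, members linearly spaced), so the contact-graph
  clustering can be checked exactly, including against a brute-force
  union-find oracle.
* `make_brownian_trajectory()` draws independent Gaussian increments
  of variance $6D\,\Delta t$ per step, the exact process behind the
  Einstein relation $\sigma^2(t) = 6Dt + A$, so the MSD machinery must
  recover the planted $D$.

These fixtures emulate the *statistical structure* the analyses
assume — they deliberately lack hydrodynamics, bonded correlations and
field-mediated interactions.  Passing them shows the analysis code is
correct, not that the physical model is; the physical claims rest on
the reduced engine runs described below.

# Analysis conventions

* **Clustering** — two molecules are connected iff *any*
  inter-molecular bead pair is within the cutoff (minimum image);
  clusters are connected components (igraph).  Bead–bead rather than
  center-of-mass connectivity is used because tail–tail contacts
  mediate the transient dimers in cyclohexane.  The cutoff is a free
  parameter (default 0.8 nm, just past the ~0.75 nm first maximum of
  the COM RDF); results are cutoff-sensitive, so it is exposed
  everywhere including the command line.
* **RDF** — standard pair-count histogram under minimum image,
  normalized per frame by the ideal-gas shell expectation, with
  optional per-molecule center-of-mass reduction (mass-weighted when
  masses are supplied).  Self-pairs are excluded for identical
  selections.
* **MSD** — averaged over particles and multiple time origins spaced
  half a lag apart (a standard bias/variance compromise); the
  diffusion fit window defaults to 10–50% of the maximum lag, and
  $R^2$ is reported as a linearity diagnostic.
* **CMC** — exhaustive ordered two-way split search with at least two
  points per side, two least-squares lines, minimum pooled residual;
  the CMC is the intersection abscissa.  Deterministic, and invariant
  under rescaling the concentration axis.  Parallel fitted lines are
  rejected rather than extrapolated.  Note the conditioning: because
  the pre-CMC regime is nearly flat, the intersection amplifies
  fractional noise on the monomer fractions by roughly the ratio of
  the concentration range to the regime-slope difference (~40x for
  the default validation geometry), so single noisy realizations
  scatter; the package's own checks therefore assert recovery as a
  median over noise replicates.
* **Scattering** — $I(Q) \propto 1 + 4\pi\rho\int (g-1) r^2
  \mathrm{sinc}(Qr)\,dr$ by trapezoidal quadrature on the binned
  $g(r)$; an unconverged tail ($|g(r_{\max})-1| > 0.05$) is recorded
  as a warning in the output rather than raised.  The
  Ornstein–Zernike fit $I_0/(1+Q^2\xi^2)$ uses Levenberg–Marquardt
  with $I_0 = \max I$ and $\xi$ seeded from the half-maximum $Q$,
  bounded below by zero so a flat curve cleanly yields $\xi = 0$.
* **Packing parameter** — $N_s = V_t/(A_c l_t)$ with the standard
  shape thresholds 1/3 (sphere/cylinder), 1/2 (cylinder/bilayer) and
  1 (bilayer/inverted).

# Reduced-scale study conditions

The published protocol uses 28 nm boxes for 100 ns; the package's own
validation runs are scaled to desk size while staying inside the same
physical regime:

* *Water self-assembly*: 10–12 nm boxes at 100 mM (60–104
  amphiphiles, ~8,000–13,600 water beads; the larger box is used where
  RDF statistics matter most), $2\times10^5$ steps (6 ns).  The
  free-monomer fraction
  decays from ~0.75 toward ~0.45 and the ADOH–ADOH center-of-mass RDF
  (0.05 nm bins, final half of the trajectory) shows a broad first
  maximum in the 0.6–0.9 nm range, the micellar contact distance.
  With only tens of molecules the aggregates are small (dimers to
  ~10-mers), so the peak is broader and sits slightly below the
  large-system value; the position is stable across seeds within a
  bin or two.
* *Cyclohexane contrast*: 8 nm box at 100 mM with charged tails and
  mesh electrostatics, same length.  No stable collapse occurs: the
  pooled cluster-size distribution stays monomer-dominated with a
  monotone, exponential-like decay.
* *Aggregation onset*: 50 mM in 8 nm vs 2 mM in 12 nm,
  $5\times10^4$ steps each — aggregation clearly present in the
  former, largely absent in the latter.  The full six-concentration
  CMC protocol is out of desk scale; the CMC fitting machinery is
  instead validated on planted two-regime data.

# Known limitations

* Particle-field dynamics are soft: short-range packing is smoother
  than atomistic reality, diffusion is intrinsically accelerated, and
  absolute time scales should not be compared to experiment.
* The bonded parameters of the amphiphile ($k_b = 1250$ kJ/mol/nm²,
  $r_0 = 0.33$ nm head–tail, 0.28 nm within the tail, no angle
  potentials) are plausible flexible-chain defaults, not fitted
  values; all are configurable.  $\kappa^{-1}$ defaults to 5 kJ/mol.
* Reduced boxes cap the attainable aggregate size; cluster-size
  distributions from them are qualitative.
* All-atom observables (solvent-accessible surface area,
  hydrogen-bond counts, atomistic diffusion coefficients) and SAXS
  form-factor modeling are outside the package's scope.
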