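---
title: "Local-move Monte Carlo sampling of united-atom phospholipids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-move Monte Carlo sampling of united-atom phospholipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmc)
```

## The problem

Atomistic molecular dynamics of lipid bilayers is limited by the femtosecond
integration step that intramolecular vibrations force on the integrator, while
the biologically interesting relaxations of a membrane (chain melting, lateral
rearrangement, head-group reorientation) happen many orders of magnitude more
slowly. Metropolis Monte Carlo removes the clock entirely: configurations are
sampled along a Markov chain whose stationary distribution is the Boltzmann
distribution, and a single "move" may cross energy barriers that a dynamical
trajectory would need nanoseconds to find. The price is that every move must
be constructed so that the chain really does converge to the Boltzmann
distribution — which is where most of the subtlety of this package lives.

`lipidmc` implements a local-move sampler for united-atom
dipalmitoylphosphatidylcholine (DPPC), a 50-site representation in which each
CH, CH2 and CH3 group is a single interaction site. All covalent bond lengths
are held fixed (the constant-bond-length approximation, CBLA), so sampling
happens in the space of bond angles and torsions; bond *angles* remain
flexible, which keeps the torsional energy landscape soft enough for dense
chain systems.

## The move set

One MC cycle visits, in fixed sequential order, all 88 sampled degrees of
freedom of each lipid (sequential updating satisfies the balance condition):

* **Chain-breakage/closure (CBC) moves** — 18 "breakage" atoms per lipid are
  displaced by a uniform random vector in a cube (3 Cartesian DOF each).
  Each bonded neighbor of the displaced atom (a "closure" atom) is
  repositioned analytically so that both of its fixed bond lengths are
  restored. The solution set of the two distance constraints is a circle;
  closure selects a point on it by a rule that is *exactly* reversible (see
  below).
* **Crankshaft rotations** — each of the 22 closure atoms carries one DOF:
  rotation about the axis through its two bonded neighbors, which preserves
  both adjacent bond lengths by construction.
* **Internal-coordinate moves** — terminal moieties (choline nitrogen with
  its methyls, chain-end methyls, phosphate and carbonyl oxygens) move by
  classical torsion (8 DOF) and bond-angle (4 DOF) perturbations of rigid
  terminal subtrees.
* **Volume moves** (bilayer only) — one isotropic rescaling of the cubic cell
  per cycle; molecular centers of mass scale affinely while intramolecular
  geometry stays rigid.

The seven external atoms (three N-methyls, two non-ester phosphate oxygens,
two carbonyl oxygens) are never moved in Cartesian space; they are rebuilt
from stored internal coordinates whenever their frame atoms move, so their
own volume elements never enter the acceptance ratio.

## Why the Jacobian, and which Jacobian

Sampling on the bond-length constraint manifold targets the measure induced
by the Cartesian Boltzmann distribution. Writing the Cartesian volume element
in terms of the sampled generalized coordinates $q$ and the constrained
coordinates $c$,
$d\Gamma = J\,\prod_i dq_i \prod_j dc_j$,
the stationary density in $q$-space is $e^{-\beta E(q)}\,J(q)$: the acceptance
rule must carry the ratio $J(\text{new})/J(\text{old})$, where $J^{-1}$ is the
determinant of the matrix of partial derivatives of the local
(sampled-plus-constrained) coordinates with respect to the Cartesian
coordinates of the moved atoms. Omitting it provably skews bond-angle
distributions — the package ships a diagnostic switch
(`run_config(use_jacobian = FALSE)`) whose only purpose is to demonstrate
this; the test suite shows that the sampled angle marginal of a 4-atom chain
matches 1-D quadrature of $\sin\theta\,e^{-\beta E(\theta)}$ to a
Kolmogorov–Smirnov distance below 0.01 with the correction, and beyond 0.05
without it.

The closed forms used per closure atom are (with $\rho$ the radius of the
two-sphere solution circle, $\gamma$ the bond angle at the closure atom,
$l$ a fixed bond length):

| closure case | free local coordinate | $J$ |
|---|---|---|
| anchored (default) | circle angle about the anchor axis | $\rho/\sin\gamma$ |
| anchored (`anchor_angle` rule) | bond angle at the anchor | $l_{CA}/\lvert w\cdot(u_a\times u_b)\rvert$ |
| terminal neighbor | bond direction (solid angle) | $l^2$ (constant) |

Bond-angle moves carry the volume-element factor
$\sin\theta_\text{new}/\sin\theta_\text{old}$; torsions and crankshaft
rotations are volume-preserving. All closure Jacobians are validated against
central finite differences (step $10^{-6}$ Å) in the test suite.

## Exactly reversible closure

A closure rule must satisfy microscopic reversibility: applying the exact
reverse displacement has to recover the prior coordinates, not merely come
close, otherwise the reverse-proximity feasibility check would reject every
finite move. Choosing the point on the solution circle *nearest* the old
position fails this test — the nearest-point projection composed with its
reverse misses the original position at second order in the step (about
$10^{-2}$ Å for 0.5 Å steps), which is why `lipidmc` uses preserved-coordinate
closures instead:

* **Default (`lab_angle`)**: the circle angle of the closure atom about the
  anchor axis, measured against a deterministic laboratory reference, is
  preserved. The solution is unique, exists whenever the two spheres
  intersect, and the rule is exactly reversible by construction.
* **Alternative (`anchor_angle`)**: the bond angle at the anchor toward its
  fixed chain continuation is preserved, giving two analytic solutions of
  which the one nearer the old position is taken (a proximity criterion over
  a *discrete* pair, with the reverse-proximity check guarding branch flips).
  This rule is physically appealing — the preserved coordinate is exactly the
  crankshaft DOF — but it is **singular at planar geometry**: at trans
  torsions its two solutions coincide, and from an all-trans start nearly
  every proposal is geometrically infeasible. Since the acyl chains of DPPC
  live near trans, the rule cannot drive the crystalline starts used here,
  and it is therefore not the default. It remains available through
  `compile_move_plan(..., closure_rule = "anchor_angle")` and is validated by
  the same quadrature test on a 6-atom chain initialized away from planarity.

The exposed geometric primitive `solve_closure()` implements the plain
two-sphere intersection with the nearest-point proximity rule; it is the
building block and reference for the circle geometry, while the breakage
proposal itself uses the reversible rules above.

## Energies and the implicit solvent

Nonbonded interactions are 6-12 Lennard-Jones
($\varepsilon_{ij}[(R_{min}/r)^{12} - 2 (R_{min}/r)^6]$, Lorentz–Berthelot
style combination of per-type parameters) plus Coulomb terms screened by a
sigmoidal distance-dependent dielectric

$$\epsilon(r) = d - \frac{d-1}{2}\left[(sr)^2 + 2sr + 2\right]e^{-sr},$$

which rises from $\epsilon(0)=1$ (no screening at contact) to the bulk-water
plateau $d = 78$. The slope $s$ (1/Å) controls how quickly full aqueous
screening is reached: $\epsilon(10\,\text{Å}) = 74.69$ for $s = 0.65$ but
only $15.72$ for $s = 0.15$. Two conventions circulate for the argument of
the polynomial and exponential ($sr$ versus $r/s$); this package uses $sr$,
the convention under which those checkpoint values are reproduced. The
default production slope is $s = 0.654$. The dielectric is applied to the
interatomic pair distance (`dielectric_mode = "pair"`); a mode that screens
by the pair midpoint's height above the bilayer midplane is provided for
comparison (`"interface"`), and `"constant"` fixes $\epsilon = 1$.

1-2 and 1-3 bonded pairs are excluded; 1-4 pairs are scaled by the
parameter-file factors (defaults 0.5 for LJ and 1/1.2 for Coulomb, the AMBER
convention — the parametrization names no explicit choice, so the family
default is used). Nonbonded interactions are truncated at a plain 10 Å cutoff
with a 10 Å Verlet shell; pairs between 10 and 20 Å are kept in the list and
gated by their current minimum-image distance, so energies between the
10-cycle list rebuilds are identical to a fresh-list evaluation. Bonded terms
are harmonic bond angles, AMBER-type Fourier torsions
$\tfrac{V}{2}(1+\cos(n\phi-\gamma))$, and Ryckaert–Bellemans cosine
polynomials $\sum_k c_k \cos^k\psi$ (with $\psi = \phi - 180^\circ$) for the
acyl-chain torsions. There is no bond-stretch term.

## Force-field parameters

The original parametrization this model emulates is not publicly tabulated,
so the package ships its own plausible AMBER-style united-atom parameter file
(`inst/extdata/dppc_ua.prm`) as the single source of truth: united masses and
electron counts are exact for C40H80NO8P (molecular weight 734.05, 406
electrons), partial charges form a neutral zwitterion (choline positive,
phosphate negative), and LJ/angle/torsion constants are generic values for
the respective chemistries. Quantities that depend on the specific
parametrization (absolute energies, equilibrated bilayer thickness, area per
lipid) are therefore *demonstration outputs*, not reproductions of published
numbers; structural bookkeeping, sampling correctness and all estimator
checks are parametrization-independent. Users can edit the file — every
value, including the z-matrix used to build start structures, is plain text.

## Start structures

`build_monomer_start()` constructs the all-trans conformation from the
equilibrium internal coordinates in the parameter file: all chain torsions at
exactly 180°, every bond at its fixed length (constructed, not fitted). The
four torsions at the glycerol branch are set so that both acyl chains run
parallel to $-z$ with no steric contact below 2.5 Å; they were chosen once by
a geometric search over branch torsions and are recorded in the parameter
file. `build_bilayer_start()` places two opposed leaflets on lattices inside
a cubic cell (n per leaflet on a $\sqrt{n}\times\sqrt{n}$ square lattice, or
an explicit rectangular layout such as 8x4 for 32), tails inward, each lipid
rotated by a seed-determined uniform angle about the vertical axis through
its own center of mass — which keeps leaflet centers of mass exactly
mirror-symmetric about the midplane. The default lattice spacing of 10 Å
gives a starting area per lipid of 1.0 nm², appropriate for a loosely packed
crystalline start that the NPT volume moves then compress.

## Ensembles, step sizes and defaults

The monomer samples NVT (no box, no cutoff — all intramolecular pairs are
evaluated); the bilayer samples NPT at 1 atm in a 2D-periodic cubic cell
(x and y wrap, z is open; the bilayer normal is +z). Volume moves sample
uniformly in $\ln V$ and accept on
$\Delta E + P\Delta V - n_{mol} k_B T \ln(V'/V)$; with this pairing the
ideal-gas stationary density is $p(V)\propto V^{n-1}e^{-\beta PV}$, so
$\langle V\rangle = n k_B T/P$ exactly — the property the NPT test checks to
2%.

Default maximum step sizes were tuned once to the 40–50% monomer acceptance
band and then frozen: breakage 0.05 Å, crankshaft ±30°, torsion ±30°,
bond angle ±8°, $|\Delta \ln V| \le 0.02$. The default temperature is 323 K
(the fluid-phase reference temperature for DPPC) and the default pressure
1 atm. All randomness flows from one integer seed; identical seeds give
byte-identical trajectories.

## Observables

* **Energy statistics** — per-cycle potential energy (monomer) or enthalpy
  $E + PV$ (bilayer); `fit_energy_histogram()` fits a Gaussian by nonlinear
  least squares and `heat_capacity()` applies the fluctuation formula
  $c = \sigma^2/(k_B T^2)$. (A Gaussian energy histogram is the expected
  equilibrium signature: the density of states times the Boltzmann factor.)
* **Schlitter entropy** — `covariance_matrix()` over saved frames and
  $S = \tfrac{k_B}{2}\ln\det\!\big(\mathbf 1 + \tfrac{k_B T e^2}{\hbar^2}
  M^{1/2} C M^{1/2}\big)$, an upper bound that reduces to
  $\tfrac{k_B}{2}\ln(1 + k_B T e^2 m \sigma^2/\hbar^2)$ in one dimension
  (the form the 1% closed-form test uses). No roto-translational superposition
  is applied by default; `superpose = TRUE` removes the center of mass first
  and changes the result, as it must. Free energy is $F = E - TS$.
* **Torsion distributions** — percent occupancy in 5° bins for the named
  head-group torsions (alpha1–alpha6 along the phosphocholine arm, beta1 and
  beta4 at the glycerol-ester linkages), averaged over molecules and frames.
* **Electron density profile** — each united atom contributes a Gaussian of
  its electron count with variance equal to its van der Waals radius value
  (in Å, read as Å of variance), divided by the lateral box area; the
  head-to-head distance `d_hh` is the separation of the two spline-smoothed
  maxima within a configurable head-group band.
* **P–N vector** — angle of the phosphorus-to-nitrogen head-group vector to
  the bilayer normal.
* **Area per lipid and K_A** — lateral box area over lipids per leaflet;
  the area compressibility modulus $K_A = k_B T \langle A\rangle /
  \mathrm{Var}(A)$ from total-leaflet-area fluctuations, in mN/m.
* **MSD** — origin-averaged lateral mean square displacement of never-wrapped
  molecular centers of mass; `msd()` fits $\mathrm{MSD} = 4 D s$ on a lag
  window. $D$ is per MC cycle and carries no physical-time meaning; it
  measures lateral scrambling efficiency, nothing more. The estimator
  normalizes by the number of lag origins (the standard time-averaged form).

On the heat capacity: the verbal recipe "square the standard deviation and
multiply by $\beta$" is dimensionally inconsistent with a heat capacity; the
package implements the standard fluctuation formula $\sigma^2/(k_B T^2)$ and
makes no claim to reproduce externally printed heat-capacity values.

## What the test systems do and do not show

The quantitative acceptance checks run on systems small enough for a desktop
core: a 4-atom chain against 1-D quadrature ($10^6$ samples), the 50-atom
monomer ($10^5$ accepted moves for bond-length conservation; 6000 cycles for
the equilibrium-signature checks), a 20-particle ideal gas ($10^5$ volume
moves), synthetic Gaussian and random-walk series for the entropy and MSD
estimators, and an 8-lipid bilayer patch for profile normalization. These
validate the sampler's statistical correctness and the estimators'
definitions. They do not demonstrate converged bilayer thermodynamics: a
fluid-phase 64-lipid bilayer needs $10^4$–$10^5$ cycles (days of CPU), and
absolute values of $D_{HH}$, area per lipid, $K_A$ or equilibrium energies
depend on the shipped parametrization. The `lipidmc run` command line drives
such long demonstrations; their outputs are reported, never asserted.

## Numerical choices and degenerate inputs

* Closure feasibility: anchors farther apart than the sum of the two bond
  lengths (or closer than their difference) make the move infeasible; it is
  rejected but counted as attempted. Bond angles driven to 0 or 180° are
  infeasible (the volume element vanishes). Non-finite energy differences
  reject with a warning.
* The reverse-proximity check compares at $10^{-9}$ Å; the CBLA watchdog
  aborts a run if any bond deviates by more than $10^{-6}$ relative,
  dumping the offending frame.
* Covariance matrices are symmetrized before the eigendecomposition; a
  non-positive-definite $\mathbf 1 + \text{(weighted covariance)}$ raises an
  error with a condition report.
* `d_hh` peak finding uses a smoothing spline restricted to a head-group
  band; fewer than two resolvable maxima yield `NA` plus a flag rather than
  a number.
* Degenerate histogram fits (constant series) and too-short MSD fit windows
  raise errors rather than returning noise.

## Known limitations

Plain cutoff electrostatics (no Ewald or reaction field) and a radially
sigmoidal dielectric are crude for a charged interface; the bilayer patch is
small and its undulation spectrum is not meaningful at this size; the
anchor-angle closure rule degenerates at trans torsions (documented above);
and MC "time" is not physical time. The shipped parametrization is a
stand-in constructed for this package, suitable for method validation and
qualitative demonstrations.
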