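---
title: "Models and methods in mmforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mmforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmforge)
```

This vignette is the package's account of the science it implements: the
potential energy model and its assumptions, the optimisation and dynamics
machinery, the crystal lattice sum, the knowledge-based scoring functions,
and the numerical and design choices made where more than one reasonable
option existed.

## The potential energy model

`energy_and_gradient()` implements the standard AMBER/GAFF functional form:
harmonic bonds $k_b(r-r_0)^2$ and angles $k_\theta(\theta-\theta_0)^2$
(note: no factor of $1/2$ — the AMBER convention), cosine torsion series
$\sum_n (V_n/2)(1+\cos(n\phi-\gamma))$, 12-6 Lennard-Jones with
Lorentz–Berthelot combining ($\sigma_{ij}$ arithmetic, $\epsilon_{ij}$
geometric), and damped-shifted-force (DSF) electrostatics.  Units are fixed
throughout: kcal/mol, Ångström, elementary charges, with the Coulomb
constant 332.0636 kcal·Å/(mol·e²); angles are degrees at every file and
function interface and radians only inside the numeric kernels.

1-2 and 1-3 pairs are excluded from the nonbonded sum and 1-4 pairs are
scaled by 1/2 (LJ) and 1/1.2 (Coulomb), the AMBER convention.  The pair
loop is the $O(N^2)$ reference implementation with a distance cutoff; at
the system sizes this package targets (tens to a few thousand atoms) a
neighbour list is unnecessary, and keeping a single code path makes the
pair set trivially auditable.

### Damped-shifted-force electrostatics

For $r \le R_c$,

$$E = C q_1 q_2\left[\frac{\mathrm{erfc}(\alpha r)}{r}
 - \frac{\mathrm{erfc}(\alpha R_c)}{R_c}
 + \left(\frac{\mathrm{erfc}(\alpha R_c)}{R_c^2}
 + \frac{2\alpha}{\sqrt\pi}\frac{e^{-\alpha^2R_c^2}}{R_c}\right)(r-R_c)\right]$$

and $E = 0$ beyond.  Both the energy and its radial derivative vanish
continuously at the cutoff, which is what makes truncation acceptable
without Ewald summation.  Defaults are $R_c = 9$ Å and $\alpha = 0.2$ Å⁻¹,
the values commonly used in the DSF literature; both are exposed through
`nonbonded_settings()`.  Note that the energy-and-force shift perturbs the
plain Coulomb value at short range by terms of order $r/R_c$, so the
undamped form converges to $Cq_1q_2/r$ only in the limit $r/R_c \to 0$.

Torsion gradients use the standard four-point analytic formulas; the sign
convention follows the package's dihedral definition (IUPAC, cis = 0°,
measured through the $\mathbf{n}_1\times\hat{\mathbf{b}}_2$ auxiliary),
which negates the textbook end-atom expressions.  The master correctness
test for the whole module is agreement with central finite differences
($h = 10^{-5}$ Å, tolerance $10^{-6}$ kcal/mol/Å) on every fixture,
together with translational invariance (gradient sums to zero) and zero
net torque.

### Charges

Published biomolecular charge sets come from electrostatic-potential
fitting, which is out of scope here.  `assign_simple_charges()` implements
a transparent stand-in: each bond transfers $s(\chi_j-\chi_i)$ elementary
charges toward the more electronegative partner (Pauling scale,
$s = 0.16$ e per unit), after which each charge group is shifted uniformly
to its formal charge.  The scheme is symmetric, deterministic, and gives
chemically sensible signs (O and N negative, their hydrogens positive);
it is not claimed to reproduce any published charge model.  Charge groups
default to one group per residue — the simplest neutral-group partition —
and neutrality is enforced to $10^{-6}$ e whenever a system is marked
neutralised.

## Minimisation

Two optimisers are provided, mirroring the division of labour customary in
molecular mechanics codes: limited-memory BFGS (two-loop recursion, history
$m = 10$, Armijo backtracking line search) for large systems, and a
Powell–Beale restarted conjugate-gradient method for small molecules and
crystals.  The CG direction is the Hestenes–Stiefel update plus Beale's
three-term restart direction, with Powell's restart test
$|g_k\!\cdot\!g_{k-1}| \ge 0.2\,|g_k|^2$; the line search is a secant
iteration on the directional derivative, which is exact on quadratics —
the classical finite-termination property (an $n$-dimensional convex
quadratic in at most $n$ iterations) is verified in the test suite.
`minimize()` picks L-BFGS above 400 atoms by default and CG below,
overridable.

Convergence is declared on the **mean per-atom gradient norm** over free
atoms, in (kcal/mol)/Å.  An RMS-gradient criterion would be a defensible
alternative; the mean was chosen because it is what a per-atom
gradient-threshold printout naturally reports, and the definition is
documented here precisely so results can be compared.  The default
tolerance is 0.5 (kcal/mol)/Å with 0.1 as the tighter setting used in the
relaxation protocols.

Atom freezing removes frozen coordinates from the optimisation vector
entirely, so frozen atoms are bit-identical on output — this implements
the rigid-receptor/flexible-ligand protocol (`minimize_complex()`), whose
headline diagnostic is the non-superposed heavy-atom RMSD between input
and relaxed coordinates (`rmsd_heavy()`).  On strongly curved landscapes
such as a ligand sliding inside a cage, restarted CG degenerates toward
steepest descent and converges slowly; the complex protocol therefore uses
L-BFGS, consistent with its role as the protein-scale optimiser.

## Molecular dynamics

`run_md()` integrates velocity Verlet with masses in amu, time in fs and
the single conversion constant 1 kcal/mol/(Å·amu) = 4.184·10⁻⁴ Å/fs².
Temperature is $T = 2E_k/(N_{dof}k_B)$ with $k_B = 0.0019872041$
kcal/(mol·K) and $N_{dof} = 3N-3$ (centre-of-mass momentum is removed at
initialisation and conserved thereafter).  The Berendsen thermostat scales
velocities after each step by $\lambda=\sqrt{1+(dt/\tau)(T_0/T-1)}$;
$\tau \to \infty$ reproduces the unthermostatted trajectory bitwise.
Defaults $dt = 1$ fs and $\tau = 100$ fs are conventional values for
all-atom MD; energy-conservation tests run at $dt = 0.1$–0.2 fs because
the stiffest motions in the fixtures are X–H stretches with ~11 fs
periods and no constraint algorithm (SHAKE) is implemented.  Periodic
boundaries are orthorhombic with the minimum-image convention; Lennard-Jones
interactions are plainly truncated at the cutoff, which is acceptable for
thermostatted runs and avoided in conservation tests by using non-periodic
clusters.

The Berendsen scheme does not sample a canonical ensemble exactly; it is
used here, as in the original programs this package models itself on, as a
robust weak-coupling temperature control.

## Crystal lattice sums

A crystal is a `unit_cell` (cell matrix built with **a** along x, **b** in
the xy-plane) plus its Cartesian contents.  The crystalline environment is
approximated by a 5 × 5 × 5 grid of copies of the unit cell with the
reference cell at the centre: 124 image interactions, each halved to avoid
double counting.  Electrostatics between cell and image are summed over
**neutral charge groups**: a pair of groups enters whole, or not at all,
according to the distance between group centres against the nonbonded
cutoff.  Because every included group is neutral, the truncated sum is
absolutely convergent and no Ewald machinery is needed.  Whether the
image-sum LJ term should use the same group rule is not dictated by any
reference; here both LJ and Coulomb use the identical group/cutoff scheme,
which keeps the inter-image energy a single well-defined quantity (and is
what the brute-force oracle in the tests implements independently).  The
plain $1/r$ Coulomb form (not DSF) is used between groups, since group
neutrality already provides the convergence that DSF's shifts exist to
supply.

`optimize_crystal()` minimises jointly over atomic Cartesians (analytic
gradients, both "roles" of each atom — as cell atom and as generator of
its images — accumulated) and optionally the six cell parameters, whose
gradients are central finite differences with relative step $10^{-4}$;
analytic strain derivatives would be faster but are unnecessary at this
scale.  Cell contents are held in Cartesian coordinates while the cell
varies; a collapse guard aborts if the volume falls below 20% of its
starting value.  Space-group symmetry is supported as explicit operator
lists applied at expansion time (`expand_symmetry()`); the optimiser does
not constrain symmetry — broken symmetry is the user's responsibility.

## Knowledge-based scoring

`pmf_from_histogram()` Boltzmann-inverts a binned radial distance
distribution: $e(\mathrm{bin}) = -k_BT\,\ln(g_{obs}/g_{ref})$, with both
distributions normalised over the binned range, zero-count bins capped at
$+e_{max}$ (default 3 kcal/mol) and the table anchored to zero at the
cutoff bin.  Two reference states are supported: an observed bulk
histogram, and the distance-scaled ideal gas $g_{ref}\propto r^{1.61}$
(the DFIRE-style reference; the exponent is a parameter, 1.61 being the
value from the literature that introduced it).  Defaults: bin width 0.2 Å,
cutoff 12 Å, $T = 300$ K.

A subtlety the tests make explicit: a histogram estimator converges to the
**bin-integrated** potential of mean force,
$-k_BT\ln\!\big(\int_{bin} e^{-U/k_BT}r^2\,dr / \int_{bin} r^2\,dr\big)$,
not to the midpoint value $U(r_{centre})$ — at steep repulsive walls the
difference is substantial.  Recovery tests therefore integrate the
generating potential over each bin as their oracle and use 3σ multinomial
count errors (including the anchor bin's noise) as tolerance.  The
Metropolis sampler behind `make_synthetic_histograms()` uses a ±1.5 Å
uniform proposal and keeps every 10th state; the wide proposal and the
thinning exist to make the kept samples nearly independent, so the
multinomial error model actually applies.

`score_pose()` sums linearly interpolated table values over all
protein–ligand atom pairs within the cutoff and returns the per-pair
decomposition (the scriptable equivalent of an interactive docking score
display, including the ability to pick out high/low-scoring pairs).
Intra-ligand pairs are not scored: the score is defined over pairs of
atoms in the two distinct selections.  Atom typing is pluggable; the
shipped default types by element, and `synthetic_score_tables()` provides
a deterministic, clearly synthetic table family (a soft 8-4 well keyed to
vdW radii) for demonstrations and scan ranking when no empirically derived
tables are supplied.

Three-point alignment follows the two-rotation construction: translate
first selected atoms onto each other, rotate the 1→2 directions together,
then rotate about that axis until the third atom lies in the target
1-2-3 plane on the same side.

## Rotamers, protons and surfaces

The side-chain model is a set of internal-coordinate templates for the 20
standard residues: heavy atoms placed by bond/angle/dihedral references,
with χ-dependent dihedrals resolved at build time, plus per-atom hydrogen
counts and hybridisations from which riding protons are constructed
geometrically (tetrahedral 109.47°, trigonal 120°, staggered methyls,
anti hydroxyls).  Five-membered rings close only approximately under
ideal-value placement; the generic force-field parameters make no claim
of ring-closure exactness.  Mutation keeps the backbone (N, CA, C, O)
fixed and rebuilds the side chain at the library's first rotamer.

The built-in rotamer library is the three-state gauche⁻/gauche⁺/trans
scheme: the Cartesian product of {−60°, +60°, 180°} over the residue's
rotatable χ bonds, giving 1 rotamer for Gly/Ala up to 3⁴ = 81 for Lys.
Proline's ring fixes its side-chain torsions, so it is treated as a
single-rotamer residue.  External libraries load from a simple text format
(`RES χ1 [χ2 …]` per line); no published library is bundled.

`rotamer_scan()` enumerates the full product over at most six residues
(a guard refuses more than 10⁶ combinations), applies each combination,
scores it against the environment **and** against the other scan residues
(both interaction classes included — the more conservative reading), keeps
the best ten by stable sort, and optionally appends force-field rescoring
without reordering the primary ranking.  Surrounding-residue relaxation is
realised by adding neighbours to the selection rather than by any implicit
mechanism.

Polar-hydrogen optimisation grid-searches hydroxyl/thiol/amine torsions in
10° steps on the force-field energy, evaluates His/Gln/Asn flips as exact
180° rotations of the terminal group about the last χ axis (an involution,
verified to restore coordinates to 10⁻⁹ Å), chooses His protonation among
δ/ε/doubly-protonated variants, and sweeps sites to convergence (at most
10 sweeps).  Ties keep the input state; the His default on degenerate
energies is the ε-tautomer, the more common tautomer in folded proteins.

Surface areas use Shrake–Rupley sampling on a deterministic golden-spiral
point set (default 960 points, probe 1.4 Å, Bondi-style radii).  The polar
surface area is the accessible area of N and O atoms plus hydrogens bonded
to them — for a molecule with no N or O it is exactly zero, and for water
it equals the total area.  Areas are rotation-invariant only up to the
angular resolution of the point set (≈0.1% at 960 points).

Ramachandran classification uses deliberately coarse two-level region
polygons (α and β favoured basins, dilated allowed regions plus the
left-handed helix); agreement with published high-resolution contours is
not claimed, and the point-in-polygon lookup is piecewise constant by
construction.

## Fixtures and what the tests do (and do not) show

All test inputs are generated in code: a generic element-typed parameter
set (bond $r_0$ = covalent-radius sums, generic 109.5° angles, one 3-fold
wildcard torsion per central pair, element LJ parameters), ideal-geometry
polyalanine built residue-by-residue at the requested φ/ψ, a rigid
spherical cage with a three-atom flexible ligand as the docking pocket, a
one-atom cubic LJ crystal whose optimal lattice constant is found by
golden-section scan at build time, a two-charge ionic cell, a 64-particle
LJ fluid at reduced density 0.5 (argon-like well depth, so that
$T_0 = 120$ K sits near $\epsilon/k_B$), and Metropolis-sampled distance
histograms.  Problem sizes were chosen so the full suite exercises every
engine in about a minute: peptides of 2–5 residues, 27–64-particle fluids,
5000-step thermostat runs, 60 000-sample histograms.

Passing these tests demonstrates internal correctness — exact gradients,
oracle-matching lattice sums, recovery of known potentials, contract-level
behaviour of every operation — on idealised inputs.  It does not
demonstrate accuracy against experimental structures: the parameter set is
generic rather than fitted, the charge scheme is a stand-in, the score
tables are synthetic, and no claim is made that relaxed geometries or
scan rankings reproduce those of production force fields.  The protocol
machinery (rigid receptor, flexible ligand, dual gradient tolerances) is,
however, exactly the one a production parameterisation would plug into.

## Known limitations

- No Ewald/PME summation; the neutral-group supercell sum is the only
  long-range treatment, and non-neutral groups are refused.
- No constraint algorithms in MD, so the stable time step is set by X–H
  stretches; no pressure coupling.
- Bond perception is distance-based (1.3 × covalent-radius sum, one bond
  per hydrogen) with no bond-order model; aromaticity is inferred only as
  5/6-ring membership for hydrogen placement.
- Insertion/deletion of residues with loop closure, nucleic-acid editing,
  mmCIF/MOL2/SDF input, and automated global docking are out of scope.
- The CG minimiser's finite-termination property holds on quadratics; on
  strongly anharmonic landscapes it restarts frequently and L-BFGS should
  be preferred.
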