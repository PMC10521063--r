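---
title: "Methods: quantum similarity, rigid superposition, reactivity descriptors and field-based QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum similarity, rigid superposition, reactivity descriptors and field-based QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqsar)
```

## Scope and model overview

`mqsar` implements the computational core of a comparative binding study of
a congeneric ligand series — prototypically geldanamycin analogues, a
family of benzoquinone ansamycin macrocycles that inhibit the Hsp90
chaperone by occupying its N-terminal ATP pocket — against the residues of
a binding site. Five method blocks cooperate:

1. **Promolecular Gaussian densities.** The molecular electron density is
   approximated as a sum of spherical atomic terms, one normalised
   s-Gaussian per atom carrying the atomic number as its electron count:
   $\rho(\mathbf r) = \sum_a N_a (\alpha_a/\pi)^{3/2}
   e^{-\alpha_a|\mathbf r - \mathbf c_a|^2}$.
2. **Molecular quantum similarity measures (MQSM).** For two densities,
   $Z_{AB} = \iint \rho_A(\mathbf r_1)\,\Omega(\mathbf r_1,\mathbf r_2)\,
   \rho_B(\mathbf r_2)\,d\mathbf r_1 d\mathbf r_2$ with the Dirac-delta
   (overlap) or Coulomb operator, plus the Carbó index
   $C_{IJ} = Z_{IJ}/\sqrt{Z_{II}Z_{JJ}}$ and the distance family
   $D_{IJ}(k,x) = [k(Z_{II}+Z_{JJ})/2 - xZ_{IJ}]^{1/2}$ (Euclidean at
   $k=x=2$; the infinite-order member is $\max(Z_{II},Z_{JJ})$).
3. **Topo-geometrical superposition (TGSA-style).** Rigid pairwise
   alignment on the common heavy-atom substructure via bonded atomic
   pairs, distance-compatible triads, and least-squares (Kabsch) fitting.
4. **Conceptual-DFT descriptors.** $\mu \approx (E_\mathrm{LUMO} +
   E_\mathrm{HOMO})/2$, $\eta \approx E_\mathrm{LUMO}-E_\mathrm{HOMO}$,
   $S = 1/\eta$, $\omega = \mu^2/2\eta$ (all in eV), and condensed Fukui
   functions $f_k^\pm$ from atomic populations of the $N\pm1$ electron
   states.
5. **Per-residue interaction energies and field-based QSAR.**
   $\mathrm{I.E} = E_{AM} - E_L - E_M$ per ligand–residue pair, with
   critical-residue ranking; CoMFA-style steric/electrostatic grid fields
   regressed on pIC50 by PLS with leave-one-out cross-validation.

Everything runs on synthetic inputs with known ground truth; nothing in
the package performs quantum-chemical, docking or molecular-dynamics
calculations. Energies, orbital energies and populations are consumed
from tables produced by external engines.

## Density parameterisation

No standard atomic-shell expansion table ships with the package, so the
default density is deliberately minimal: one shell per atom with
$N_a = Z_a$ and exponent $\alpha_a = (c/r_\mathrm{cov},)^2$, with
tabulated covalent radii and a single calibration constant $c = 1.5$
(`exponent_scale`). Two properties motivated this choice: the electron
count is conserved exactly, and every similarity integral has a closed
form, so the implementation can be validated against independent
numerical quadrature to tight tolerances. The similarity *indices* —
ratios such as the Carbó index — are robust to the exponent choice (the
tests verify exact invariance under uniform electron scaling, and the
index bounds hold for any positive exponents). The absolute measures
$Z_{AB}$ are not, and no agreement with ab-initio densities is claimed;
multi-shell parameter sets can be supplied as JSON
(`read_density_parameters()`) if a fitted expansion becomes available.

The Coulomb measure uses $\mathrm{erf}(\sqrt{\mu}R)/R$ per shell pair
with $\mu = \alpha_1\alpha_2/(\alpha_1+\alpha_2)$; below
$R = 10^{-9}$ Å the analytic coincident limit $2\sqrt{\mu/\pi}$
replaces the expression to avoid 0/0.

## Superposition details

Hydrogens are excluded throughout. Triads are generated as bonded
extensions of bonded heavy-atom pairs (not all atom triples), which caps
the combinatorics at chemically meaningful candidates; near-collinear
triads (triangle area below 0.05 Å²) are discarded because three nearly
collinear points do not determine a rotation. Two triads match when a
vertex correspondence exists with equal elements and side lengths within
`tol` (default 0.30 Å — a value of the order of a bond-length
fluctuation; no published value exists for this tolerance, so it is
exposed as an argument). Each matched triad seeds a Kabsch fit, grown
greedily (nearest unclaimed same-element atom within `tol`, by increasing
distance) and refit on all matched pairs. Tie-break between candidate
alignments is deterministic: most matched atoms, then lowest rmsd, then
lexicographically smallest seed-triad atom ids.

The alignment quality index is
$C_{IJ} = d_{IJ}/\sqrt{d_{II}d_{JJ}}$ with
$d_{XY} = \sum_i\sum_j \exp(-|\mathbf x_i - \mathbf y_j|^2)$ over the
superposed heavy atoms. The original description of this cost is
typographically corrupted in the source literature; this Gaussian-kernel
form is a declared reconstruction chosen because it provably satisfies
every property asserted of the index: it lies in $[0,1]$ by
Cauchy–Schwarz (the Gaussian kernel is positive definite) and equals 1
exactly at structural identity. Molecules are treated as rigid bodies;
input coordinates are never modified. Flexible (torsional) alignment is
out of scope.

## Reactivity descriptors

Softness is implemented as $S = 1/\eta$ (not $1/2\eta$): this is the
convention under which the package's reference descriptor table for the
geldanamycin analogue series is internally consistent (e.g.
$1/5.4932 = 0.1820$). Descriptor tables are printed to 4 decimals with
half-away-from-zero rounding, matching the formatting of the published
tables this layout mirrors; full precision is kept internally. Condensed
Fukui functions interpret the $q_k$ columns as atomic *electron
populations*; net-charge input is accepted with `input = "charge"` and
sign-converted. When the population table conserves the transferred
electron, $\sum_k f_k^\pm = 1$ exactly, which the generated tables
satisfy by construction.

## Interaction-energy decomposition

`I.E` is a pure table computation: $E_{AM} - E_L - E_M$ with all three
energies in one unit (kcal/mol by default; the unit is metadata because
upstream semi-empirical engines differ in what they report, and heats of
formation versus total energies cancel identically in the difference).
"Critical" residues have no published operational definition; the package
ranks residues by mean I.E across ligands (ascending, ties broken by
name) and flags the `top_n = 4` most favourable — four matching the
number of pocket residues typically singled out in this class of study
(Lys58, Asp54, Asp93, Lys112 in the reference system). Decimal commas in
pasted literature values are normalised on ingest.

## Field-based QSAR

Field conventions follow published CoMFA practice, since the commercial
implementation's exact functional forms are proprietary: an sp³-carbon
probe with +1.0 e charge, 2.0 Å default grid spacing with 4 Å margin,
Lennard-Jones 6–12 steric field, Coulomb electrostatic field with
distance-dependent dielectric $\varepsilon = r$ (hence $332.0636\,q_iq_p
/ r^2$ kcal/mol), both capped at ±30 kcal/mol, and near-constant columns
(sd < 0.05) dropped. All of these are arguments. Blocks are CoMFA-std
scaled so steric and electrostatic columns enter the regression with
equal weight; field contributions are reported as
$\sum_j |b_j|\,\mathrm{sd}_j$ per block, normalised to 100 %.

PLS is univariate-response NIPALS on centred data. Its correctness is
cross-checked in the test suite against the independent Krylov-subspace
characterisation of PLS1 (the $k$-component solution is the least-squares
fit restricted to
$\mathrm{span}\{X^\top y, (X^\top X)X^\top y, \dots\}$). A consequence
worth noting: for a noiseless activity that is linear in a few columns of
a *generic* dense matrix, $k$ components generally do **not** give an
exact fit — PLS needs as many components as the Krylov grade of the
signal. The exact-fit property holds when the component count reaches the
rank of the relevant column space, which is how the tests exercise it.
Cross-validation is full leave-one-out refitting (PRESS against the
overall activity mean), the convention behind published $q^2$ values for
small congeneric series; SAMPLS-style shortcuts are not used.
Contribution contours partition grid points at order-statistic percentile
levels (default 20 %/80 %) of the signed $b_j\,\mathrm{sd}_j$ product,
the favourable/unfavourable contour pair of CoMFA maps.

## Synthetic scenarios: what they emulate, and what they do not

The generator mirrors the study design: a rigid 12-membered macrocyclic
scaffold shared *exactly* across the series (the macrocycle is kept rigid
in the reference workflow), substituents drawn from a small library at
two designated sites (the C-11/C-17 analogy), a pocket of small
pseudo-residues with fixed partial charges, and an additive pairwise
Hamiltonian $4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
332.0636\,q_1q_2/r$ with $\epsilon = 0.1$ kcal/mol, $\sigma = 3.4$ Å.
Additivity is the point: $E_{AM} = E_L + E_M + E_\mathrm{inter}$ holds
exactly, so the per-residue decomposition has a brute-force oracle.
Activities are planted as a linear function of the three highest-variance
field columns, rescaled to the pIC50 span [5.57, 8.04] observed for the
reference assay set, with Gaussian noise (default $\sigma = 0.1$, a
realistic assay reproducibility on the pIC50 scale); 40 ligands matches
the size of the reference series (43 analogues). Every generator is a
pure function of its seed and restores the caller's RNG state.

What passing tests on these scenarios do **not** show: agreement with
any published absolute similarity value, interaction energy or $q^2/R^2$
statistic. Those depend on unpublished 3D structures, proprietary field
implementations and semi-empirical engines, and are explicitly out of
scope; the suite substitutes property-based checks (oracle equivalence,
transform recovery, parameter recovery, permutation collapse) run at
sizes chosen for desk-scale reproducibility: 10 quadrature pairs, 20
alignment recoveries, a 40-ligand QSAR scenario with 50 permutation
replicates.

## Numerical choices and degenerate inputs

* Rounding for printed tables: half away from zero, 4 decimals.
* Coulomb coincident-centre branch at $R < 10^{-9}$ Å.
* Generalised distance: a negative radicand (possible only for
  inconsistent hand-supplied $Z$ values) is an error, not an NaN.
* Alignment with no distance-compatible triad, or whose best seed extends
  to fewer than 3 atom pairs, fails loudly; the pairwise similarity
  matrix records such pairs and leaves their entries `NA` rather than
  silently substituting unaligned measures.
* Grid axes are extended so the box always reaches the requested margin;
  a molecule outside the grid is an error.
* Near-constant field columns are dropped once, before model fitting, so
  leave-one-out folds see a fixed column set.

## Known limitations

* The one-Gaussian-per-atom density is a coarse shape model; only
  index-level (ratio) comparisons should be interpreted.
* The superposition algorithm assumes a shared heavy-atom substructure
  and rigid geometries; element-disjoint or highly flexible pairs fail by
  design.
* The toy Hamiltonian has no polarisation, solvation or directional
  hydrogen-bond term; its purpose is exact decomposability, not physical
  fidelity.
* `rank_critical` operationalises "critical residue" as a rank threshold;
  it is a screening aid, not a significance test.
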