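---
title: "Accelerated-MD boosting, reweighting, and contact-based PCA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated-MD boosting, reweighting, and contact-based PCA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdtools)
```

amdtools re-implements, as reusable and testable machinery, the analysis
workflow of accelerated molecular dynamics (aMD) studies of protein–RNA
recognition, of the kind used to characterise how a YTH reader domain
distinguishes N6-methyladenosine (m6A) RNA from its unmethylated
counterpart. The microsecond explicit-solvent simulations themselves are far
out of desk scope; what the package provides is everything downstream of
them — the boost/reweighting mathematics, RMSD and PCA trajectory analysis,
native-contact analysis and contact-based PCA — plus a synthetic data
generator that emulates the statistical structure those analyses assume, so
the whole chain can be validated end to end without any simulation data.

## The aMD boost potential

aMD enhances sampling by raising the potential wherever it falls below a
threshold $E$:

$$V^*(r) = V(r) + \Delta V(r), \qquad
  \Delta V(r) = \begin{cases}
    \dfrac{(E - V(r))^2}{\alpha + E - V(r)} & V(r) < E \\
    0 & V(r) \ge E
  \end{cases}$$

`boostDeltaV()` implements $\Delta V$ and `boostFactor()` its consequence
for forces, $dV^*/dV = \alpha^2/(\alpha + E - V)^2 \in (0, 1]$. Two
properties are load-bearing and are tested explicitly: $V^*$ is continuous
and once-differentiable at $V = E$, and for $V < E$ the boosted surface
stays below $E$ while remaining strictly increasing in $V$ (monotone
flattening — wells rise more than barriers, so transitions accelerate as
$\alpha$ decreases).

### Dual-boost parameters from conventional-MD averages

Production aMD applies one boost to the dihedral energy term and a second to
the total potential. `estimateAmdParameters()` implements the standard
size-scaled heuristic on conventional-MD energy averages:

* $E_\mathrm{tot} = \langle V_\mathrm{tot}\rangle + 0.16\ \mathrm{kcal\,mol^{-1}\,atom^{-1}} \times n_\mathrm{atoms}$
* $\alpha_\mathrm{tot} = 0.2\ \mathrm{kcal\,mol^{-1}\,atom^{-1}} \times n_\mathrm{atoms}$
* $E_\mathrm{dih} = \langle V_\mathrm{dih}\rangle + 3.5\ \mathrm{kcal\,mol^{-1}\,residue^{-1}} \times n_\mathrm{residues}$
* $\alpha_\mathrm{dih} = 0.2 \times 3.5\ \mathrm{kcal\,mol^{-1}\,residue^{-1}} \times n_\mathrm{residues}$

The atom count is taken verbatim (solvated-system counts, water included);
the residue count is protein residues plus nucleotides. Internal values keep
full precision; `amdParameterTable()` rounds to the nearest integer for
reporting, which is the convention of the published parameter blocks. For
the solvated YTH–m6A complex (22,552 atoms, 162 residues,
$\langle V_\mathrm{tot}\rangle = -68{,}357$,
$\langle V_\mathrm{dih}\rangle = 2016$ kcal/mol):

```{r params}
amdParameterTable(estimateAmdParameters(-68357, 2016, 22552, 162))
```

`dualBoostDeltaV()` follows the Amber dual-boost convention: the dihedral
boost is evaluated first, then the total boost on the dihedral-boosted total
potential. The toy simulator exercises only the total channel, since
analytic toy potentials have no dihedral term.

## Reweighting and free-energy surfaces

Canonical averages are recovered from a boosted run by weighting frame $i$
with $w_i \propto e^{\beta \Delta V_i}$. `reweightFrames()` stabilises the
exponential by subtracting the maximum exponent, and also offers the
Maclaurin-series variant $w_i \propto \sum_{j=0}^{k} (\beta\Delta V_i)^j/j!$,
which trades a small bias for much lower variance when $\beta\Delta V$ is
large; the two are required (and tested) to agree to $10^{-6}$ at order
$k = 30$ for $\beta\Delta V \le 5$. Which variant the original analyses used
is not documented, so both are first-class and exponential is the default.

`freeEnergySurface()` bins 1D/2D samples (toy positions or PCA projections)
into equal-width bins and sets $G = -k_BT \ln(\text{weighted density})$,
shifted so the occupied minimum is zero; empty bins are $+\infty$.
`basinBarrier()` reads off $\Delta G$ between two basin regions as the
difference of their minimum-$G$ bins, and the barrier as the minimax path
level between the two minima — the bin interval in 1D, and in 2D the lowest
level at which the basins join under 4-neighbour bin connectivity (found by
binary search over the sorted levels, i.e. a lowest-saddle search).

$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$ throughout, with $T = 300$ K
as the default, matching the production temperature of the simulations the
workflow targets.

## The Langevin toy model

`runLangevin()` integrates a 1D double well
$U(x) = h(x^2 - 1)^2 + \text{tilt}\cdot x$ (or its 2D extension with a
harmonic transverse channel) with the BAOAB splitting of Langevin dynamics,
in compiled code. Defaults: $h = 3$ kcal/mol (a barrier deep enough that
unboosted crossings are rare at 300 K but still countable), friction
1 ps$^{-1}$ (the collision frequency typical of solvated-protein
thermostats), $dt = 0.002$ ps, validated against the well curvature
$\omega = \sqrt{8h/m}$ — the run refuses to start if
$dt\,\max(\omega, \gamma) > 0.5$. Mass is in energy-consistent toy units
(kcal mol$^{-1}$ ps$^2$ Å$^{-2}$) so no unit-conversion constant appears in
the integrator. A guard radius (default 10 Å) aborts diverged runs with a
diagnostic rather than returning garbage.

When `params` are supplied, the conservative force is scaled by
`boostFactor()` evaluated on the toy's total potential — exactly the
derivative relation above — and the per-frame $V$ and $\Delta V$ are
recorded for reweighting. With a threshold below every sampled $V$, a
boosted run is bitwise identical to the unboosted run at the same seed,
which pins down the gating logic.

The validation cycle this enables (and which the acceptance checks run): an
unboosted reference run, a boosted run at $E$ set at the barrier top with
$\alpha = 1$ kcal/mol, exponential reweighting, and the requirement that the
two free-energy surfaces agree to 0.5 kcal/mol RMS over shared bins and that
the basin $\Delta G$ matches 1D quadrature of the Boltzmann factor to
0.3 kcal/mol, at $2\times10^5$ recorded samples per run. These problem sizes
keep a full check under a minute; the equilibrium checks against analytic
densities use longer runs ($10^8$ steps, recorded every 100) because
barrier crossings — about one per 5×10^5 steps unboosted — are what limit
the effective sample size. The published basin/barrier numbers for the real
systems (e.g. −6.0 and 12.3 kcal/mol for the apo domain) require the real
microsecond trajectories and are deliberately not targets here.

## Cartesian PCA of trajectories

`buildCovariance()` forms the coordinate covariance
$\sigma_{mn} = \langle (r_m - \langle r_m\rangle)(r_n - \langle r_n\rangle)\rangle$
over a selection (protein Cα by convention), after rigid-fitting every frame.
Conventions, each of which some other toolkit chooses differently, are fixed
as follows and relied on by the tests:

* **Population covariance** (divide by $F$, not $F-1$), so the variance of
  the defining ensemble's projections equals the eigenvalue exactly.
* **Fit target**: the starting/reference structure by default, matching the
  consistent use of the initial structure as RMSD reference; `fitTo = "mean"`
  re-fits to the ensemble mean (one iteration) for users who prefer
  mean-centred fitting. Which of the two the original analyses used is not
  recoverable from their description; both are supported.
* **No mass weighting** — the covariance is of bare Cartesian coordinates.
* **Sign convention**: each eigenvector's largest-magnitude component is
  positive, making plots and regression tests reproducible.
* Replicas are concatenated before averaging, the combined-trajectory
  convention (three independent runs analysed as one 3000-frame ensemble).

Rigid fitting removes six degrees of freedom, so at least six eigenvalues
must be numerically zero — an invariant the suite checks on every generated
ensemble. `projectTrajectory()` supports cross-projection: ensembles other
than the defining one (the ligand-bound analogues of an apo-defined
subspace) are projected onto the same modes to compare sampled regions.
`extremeConformations()` and `modeArrows()` support the standard
visualisation of a mode as the displacement between the most negative and
most positive projections, with ties broken to the lowest frame index.

The superposition itself (`superpose()`) is the closed-form SVD solution of
the least-squares rigid fit with reflection correction (determinant +1
enforced); it is cross-checked in the tests against both an independent
implementation (bio3d) and a grid-search-plus-refinement oracle over Euler
angles.

## Native contacts and contact-based PCA

A protein residue and a nucleotide are in native contact when the minimum
over heavy-atom pairs of their distances in the reference structure is below
6.0 Å. The workflow's two source conventions differ in wording — native
contacts are defined with strict `<`, contact *counts* "within" the cutoff
with `≤` — so `nativeContacts()` defaults to strict and
`contactCountSeries()` to inclusive, both configurable; the difference has
measure zero for real coordinates. Hydrogens never participate.
Methylated-adenosine residue names (6MA, 6MZ, M6A, A2M, …) are classified
as nucleotides via an extensible alias table. No periodic-image handling is
applied: analysis trajectories are assumed solute-only, as stripped
conformations are.

`minDistanceSeries()` evaluates the per-frame minimum heavy-atom distance
$D_{ij}$ for each native pair. `contactCovariance()` then forms
$\sigma_{ij} = \langle (D_i - \langle D_i\rangle)(D_j - \langle D_j\rangle)\rangle$
— covariance of the raw distances, not correlation and not a
switching-function contact fraction, which keeps fidelity to the printed
definition (a correlation option exists but is off by default; a contact
whose distances double contributes four times the variance, and the tests
pin this scale behaviour). `conpcaModes()` shares the eigensolver and sign
convention of the Cartesian PCA. `rankComponents()` orders one mode's
components by absolute value (ties by native contact order, signs
preserved): contacts that form or break together carry large same-signed
components on the leading mode, which `signCoherent()` tests directly.
Representative frames are taken at the projection extremes, consistent with
the Cartesian-PCA convention — how the original representative structures
were picked is not stated, so this package states its rule explicitly.

Whether per-nucleotide contact counts should count residues or atom pairs is
also not recoverable from the sources; both levels are implemented
(`level = "residue"` is the default) without asserting which matches the
published figure.

## The synthetic-data generator

`buildTemplate()` constructs a deterministic pseudo-complex: 156 protein
residues (author numbering 347–502, so the recognition loop is 431–442 and
the pocket floor 380–386), each with a Cα, 2–4 pseudo-heavy side atoms and a
hydrogen, and a 6-nucleotide RNA whose third position — the m6A analogue —
sits in the pocket. Pocket side atoms reach within contact range from below,
loop side atoms from above; the rest of the protein traces a distant shell
with no ligand contacts. The construction guarantees what the analyses need:
every loop residue forms a native contact with the ligand nucleotide (the
planted *breaking block*), pocket contacts persist in both states, and a
fixed opening direction (near +z with a small seed-derived tilt) breaks all
loop contacts when the loop is displaced along it.

`generateTrajectories()` drives a two-state (closed/open) Markov chain
rather than Langevin dynamics on a loop coordinate — deliberately, so state
occupancies have closed-form expectations usable as exact oracles. Per
frame, a closed state opens with probability $2rp$ and an open state closes
with probability $2r(1-p)$, giving stationary open fraction $p$ at switching
scale $r$. Defaults, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `openAmplitude` | 8 Å | comfortably past the 6 Å cutoff plus noise; loop-scale motion |
| `transitionRate` | 0.1 / frame | mean dwell ~10 frames: tens of state alternations per 1000-frame replica, so empirical occupancy concentrates near $p$ |
| `openFraction` | 0.5 | apo-like regime; the ligand-bound regime pins closed, partial opening uses $0.3 p$ |
| `noiseSigma` | 0.3 Å | thermal jitter well below the state separation |
| frames × replicas | 1000 × 3 | the combined-ensemble size of the target study design |

All randomness flows from the single seed (replica $k$ uses seed $+k$); the
same spec reproduces bitwise-identical output.

What the generator emulates: a two-state collective loop motion with
state-coupled contact formation, replica structure, and Gaussian thermal
noise — the statistical structure the PCA, contact and contact-PCA stages
assume. What it does not emulate: sterics, bonded energetics, anharmonic
basins, correlated noise, solvent or any force field. Passing tests
therefore demonstrate that the analysis machinery recovers planted
ground truth under the assumed statistical model, not that real
YTH trajectories would behave this way.

## Pipeline and numerical choices

`runPipeline()` orchestrates the stages from a single validated YAML config
(unknown keys rejected to guard against typos; missing keys reported
together; defaults — 6.0 Å cutoff, 300 K, Cα selection, exponential
reweighting — filled explicitly). Replicas are combined for PCA and
contact PCA but summarised per frame across replicas for RMSD, mirroring the
combined-trajectory vs replica-average split of the study design. Outputs
are plain CSV/PDB with an md5-carrying JSON manifest; the same config and
seed give byte-identical numeric outputs, which the tests assert.

Degenerate and edge inputs are handled explicitly rather than by accident:
coincident/collinear fit atoms are an error in `superpose()`; a single
replica yields `NA` standard deviations only when opted into; an empty atom
selection errors unless `allowEmpty = TRUE`; fewer than two occupied FES
bins warns of a degenerate surface; boosted-run divergence aborts with a
diagnostic.

## Known limitations

* The package analyses trajectories; it cannot produce the real ones. None
  of the published system-specific numbers (RMSD plateaus, PC1/PC2
  contribution percentages, binding free energies, basin/barrier energies)
  are reproduced — only the machinery that computes such numbers is, with
  its correctness established on toys and synthetic ground truth.
* Text formats only (multi-model PDB, whitespace coordinate tables); no
  DCD/XTC/NetCDF readers.
* The 2D barrier search operates on the binned surface; very coarse bins
  coarsen the saddle estimate accordingly.
* Contact analysis assumes solute-only coordinates; no minimum-image
  correction is applied.
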