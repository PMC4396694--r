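---
title: "Mapping multi-state free-energy landscapes with ramfes"
author: "ramfes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multi-state free-energy landscapes with ramfes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramfes)
```

## Scope and model

`ramfes` implements the computational core of a replica-averaged
metadynamics (RAM) study of a multi-state protein domain: enhanced
sampling along collective variables (CVs) under experimental restraints,
reconstruction of the free-energy surface from the accumulated bias, and
validation of the resulting ensemble against NMR observables. The
all-atom molecular dynamics layer of such a study (explicit solvent,
force fields, Ewald electrostatics) is deliberately out of scope: the
sampling engine runs on analytic toy potentials whose thermodynamics are
known exactly, so every statistical claim the package makes can be
checked against an independent oracle. The analysis layers — CVs,
restraint energetics, WHAM, basin thermodynamics, RDC and
secondary-structure validation — are the same code one would apply to
hill logs and trajectories from a production simulation.

## Collective variables

Three kinds of CV are provided.

*Dihedral correlation.* For an ordered list of dihedrals
$a_1, \dots, a_n$,
$$\mathrm{DC} = \sum_{k=1}^{n-1} \tfrac12\,[1 + \cos(a_k - a_{k+1})],$$
dimensionless, bounded by $[0, n-1]$, $2\pi$-periodic in every angle.
The literature names this CV without printing a formula; the
consecutive-pair form above is the standard metadynamics
dihedral-correlation CV and is the one implemented. Pairing follows
chain order as produced by the backbone enumeration (phi before psi
within a residue, chi1 lists in residue order); whether the original
analysis paired angles within or across residues is not recorded, and
strict chain order is adopted as the single documented convention.

*Group angle.* The orientation angle theta of a helix against a
hydrophobic core is the angle at the vertex formed by three Calpha
group centroids. The source description lists three residue groups
without naming the vertex; the middle-listed group (the anchor loop
between core and helix) is geometrically the hinge, and is therefore
taken as the vertex. Centroids are unweighted means — for Calpha-only
groups this equals the centre of mass exactly.

*Generic coordinate.* Toy-system coordinates, used by the engine.

The standard four-CV set (`buildCVSet`) biases: all backbone phi/psi
(sigma 0.1); heavy-side-chain chi1 (Phe, His, Tyr, Trp, Arg, Lys, Met)
outside helices 1 and 7 (sigma 0.1); the same chi1 set inside those
helices (sigma 0.1); and theta (sigma 0.05). The helix boundaries are
user configuration with defaults (142–156, 287–305) chosen from the
residue landmarks of the I-domain literature; published per-CV angle
counts cannot be reproduced without the original boundary choices, so
the defaults are explicitly overridable and the partition property
(cv2 and cv3 tile the full heavy-chi1 set) is what the tests pin down.

## Replica-averaged restraints

The chemical-shift restraint is
$$E_\mathrm{CS} = \sum_{i,j} E_{ij}\!\left(\bar\delta^{\,\mathrm{calc}}_{ij}
- \delta^{\,\mathrm{exp}}_{ij}\right),$$
where the calculated values are arithmetic means over replicas. The
functional form of $E_{ij}$ is cited to prior work rather than printed;
a flat-bottom harmonic (zero inside a per-atom-type tolerance, $k\,
(|\Delta|-\varepsilon)^2$ beyond, optional cap) is implemented, the
standard choice for chemical-shift restraints. Defaults are
$\varepsilon = 0.3$ ppm for proton types and $1.0$ ppm for N/C, with
$k$ configurable in kJ/mol/ppm². Because only the *average* is
restrained, individual replicas keep fluctuating: the tests verify that
a restrained toy run moves the ensemble mean toward the target while
retaining 50–100% of the unrestrained variance — the maximum-entropy
behaviour that motivates replica averaging. Real shift predictors
(CamShift, Sparta+) are out of scope; the forward-model interface
accepts any function from coordinates to observables, and a linear
model with analytic derivatives ships for exact force validation.
Index ranges (number of residues, number of shift types) are properties
of the observable table, never constants.

## Sampling engine

Each replica carries one history-dependent bias
$$V(s,t)=\sum_{k\tau<t} W\,
\exp\!\left(-\frac{(s-s^{(0)}(k\tau))^2}{2\sigma^2}\right)$$
with constant height $W$ (plain, non-well-tempered metadynamics,
matching the printed bias definition). The strict inequality
$k\tau < t$ is honoured: a hill does not act at its own deposition
instant. Dynamics are BAOAB Langevin at unit mass. This is a deliberate,
documented deviation from the Berendsen-thermostatted MD of the original
study: Berendsen does not sample the canonical ensemble exactly, and the
package's acceptance tests require correct sampling (equipartition on a
harmonic well and a Kolmogorov–Smirnov check against the quadrature
Boltzmann distribution both pass within statistical tolerance).
Configuration exchanges between replicas use the bias-exchange
Metropolis rule at a common temperature; swaps that lower the total bias
are always accepted, and the exchange preserves the configuration
multiset. Defaults — $\tau = 500$ steps, $W = 0.2$ kJ/mol, exchange
stride 2000 steps, $dt = 0.01$, friction 1 — are desk-scale choices for
the toy systems, not values from any publication (the original exchange
and deposition strides are not printed). The inner loop is compiled
(Rcpp) and draws from R's RNG, so runs are bit-reproducible from
`set.seed`; hills beyond eight sigma of the evaluation point are
skipped, an error below 1e-14 of a hill height.

## Free-energy reconstruction

CV trajectories recorded after an equilibration time $t_\mathrm{eq}$ are
binned on a regular grid (bin width defaulting to the hill sigma),
giving microstates with per-replica counts. The WHAM equations
$$p_\alpha \propto \frac{\sum_r n_{r\alpha}}
{\sum_r N_r\, e^{(f_r - V_r(s_\alpha))/k_BT}},\qquad
e^{-f_r/k_BT} = \sum_\alpha p_\alpha\, e^{-V_r(s_\alpha)/k_BT}$$
are iterated with log-sum-exp stabilisation until the normalisation
constants move by less than a tolerance (default 1e-8 kJ/mol, cap 1e5
iterations; non-convergence is an error reporting the residual). The
bias entering WHAM is the hill sum treated as static — metadynamics is
quasi-stationary after $t_\mathrm{eq}$ — optionally time-averaged over
the production window (`biasOnMicrostates`), which is the default in the
end-to-end pipeline. Free energies are gauged to min 0; empty
microstates carry $+\infty$.

Basins are found by steepest-descent watershed on the (1D or 2D)
surface; minima separated by a barrier below `min_barrier` (default
1 kJ/mol, i.e. sub-thermal wiggles at 300 K) are merged, which absorbs
the statistical roughness of reconstructed profiles. Basin populations
default to basin-restricted partition sums
$p_k = \sum_{\alpha\in k} p_\alpha$; the alternate "minima" mode
computes $p_k \propto e^{-\Delta G_k/RT}$ directly from basin offsets,
which is the arithmetic that turns the offsets 0 / 0.7 / 2.8 kJ/mol into
populations of 48 / 36 / 16% at 300 K. Whether published populations of
that kind derive from partition sums or minima offsets is ambiguous;
both modes are provided and the mode is recorded in the result.
Microstate construction here is grid-based; published microstate counts
from interactive clustering tools depend on unrecorded settings and are
not reproduced.

## Synthetic data: what it emulates, and what it does not

The generators define the package's study conditions:

* `makeTripleWell` — inverted Gaussians on a steep polynomial wall. The
  constructor *calibrates* well depths by fixed-point iteration against
  numerical quadrature until the basin free energies at 300 K match the
  requested offsets (default 0 / 0.7 / 2.8 kJ/mol, the three-substate
  spacing) within 0.01 kJ/mol, and fails loudly otherwise. A uniform
  depth shift keeps every well substantial relative to the confining
  plateau, which keeps the targets reachable in 2D where the plateau
  area is large.
* `makeStateEnsemble` — labelled frames whose marker atoms encode the
  helix angle theta and the ratchet distance exactly (state fractions
  0.48/0.36/0.16; ratchet distances 8.0/8.0/11.8 Å as the two printed
  means; theta means 20/40/30° with 3° spread, the package's own
  choice since the corresponding ranges are published only graphically).
* `makeSyntheticRDC` — couplings from a known traceless Saupe tensor
  plus seeded Gaussian noise, on a structure's N–H vectors or random
  orientations.
* `makeIdealPeptide` — poly-Ala backbones at canonical dihedrals
  (helix, extended, PPII, a hydrogen-bonded hairpin, seeded random
  coil) built by NeRF internal-to-Cartesian placement with standard
  bond geometry.
* `makeSyntheticIDomainBackbone` — a synthetic 188-residue backbone at
  author numbering 128–315: the construct length for which backbone
  enumeration yields 374 phi/psi angles. It is a labelled stand-in used
  because the deposited crystal structure is not bundled or fetched;
  it exercises the counting rule and the I/O path at realistic size,
  not the real fold's geometry.

Passing tests on these generators demonstrate that the *algorithms*
recover known ground truth under realistic noise and sampling budgets.
They do not demonstrate force-field accuracy, convergence at all-atom
dimensionality, or the behaviour of real shift predictors — none of
which the package claims.

## Validation modules

*RDCs.* The Saupe tensor is fitted by SVD of the $N\times5$
direction-cosine design matrix (rank and condition-number guarded),
conventionally on the rigid beta-strand core, and couplings of held-out
residues are scored with
$Q = \sqrt{\sum(D^\mathrm{calc}-D^\mathrm{obs})^2 / \sum
(D^\mathrm{obs})^2}$ — the sum-normalised convention; the published
analyses' exact normalisation is not printed, so the convention is
documented and the implementation is validated on constructed cases
(exact recovery at zero noise, $Q = 0.5$ for half-scale predictions,
noise monotonicity). For ensembles the default fits one tensor per
frame and averages the back-calculated couplings under the frame
weights (standard ensemble-RDC practice); a single-tensor mode fits the
weighted-average cosine products instead, and is the exact inverse of
the construction used in the two-state tests. The overall dipolar scale
$D_\mathrm{max}$ is absorbed into the tensor by default. Published Q
values for the real domain (0.36 restrained, 0.55 unrestrained, 0.28
for helix 7) require the unpublished coupling table and original
ensembles; the package covers the qualitative property that Q is
minimised at the true ensemble weights.

*Secondary structure.* A compact Kabsch–Sander assignment: amide H
built at 1.02 Å along the in-plane bisector when absent, H-bond when
the electrostatic energy $0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
1/r_{CN})\cdot 332$ kcal/mol is below −0.5, helices from consecutive
i→i+4 (H) or i→i+3 (G) turns, strands from parallel/antiparallel
bridge patterns. Pi-helices and bend/kappa classes are omitted. PPII is
not an H-bond class: unassigned residues with phi in [−110°, −50°] and
psi in [120°, 180°] are labelled P, an approximation standing in for
shift-based population inference, which is out of scope (reference
populations are consumed from file). The assigner reproduces reference
DSSP labels exactly on the helix and hairpin fixtures; those labels are
frozen as golden strings in the tests.

*Substate classification.* IA-like when the ratchet distance exceeds
10 Å (midpoint of the printed 8 and 11.8 Å means), otherwise LA-like or
AI-like by a theta split. No universal theta default is asserted — the
published ranges exist only graphically — so `theta_split` is a required
choice calibrated on the system at hand.

## Numerical choices and problem sizes

* Gas constant 0.0083145 kJ/mol/K; energies kJ/mol, distances Å,
  user-facing angles degrees (radians internally for dihedrals).
* WHAM tolerance 1e-8 kJ/mol on the replica constants; gauge fixed by
  the first replica and by min-0 free energies.
* The end-to-end recovery study uses 2 replicas × 6×10⁵ BAOAB steps
  (dt 0.02, t_eq the half-way point), bin width 0.1, and recovers the
  0 / 0.7 / 2.8 kJ/mol offsets within ±0.3 and populations within
  ±0.05 on a majority of seeds; the WHAM oracle check uses 2×10⁵
  exact-MCMC samples under two static umbrella biases derived from the
  well depths. These sizes were chosen so the statistical error sits
  comfortably inside the assertion bands at desk-scale runtimes.
* The convergence diagnostic windows hill histories and compares the
  spatial spread of newly added bias per deposition against the first
  window. Constant-height hills never reach rate zero (the filled-well
  regime adds bias uniformly but stochastically), so stationarity is
  declared at a configurable fraction (default 0.5) of the initial
  rate; the bound asserted in the tests (trailing < 45% of initial on
  the double-well fixture) is a frozen regression observation.
* `findBasins` merges across sub-threshold barriers relative to the
  shallower minimum; on noiseless analytic grids it reports exact basin
  counts and offsets at grid resolution.

## Known limitations

* The engine's toy potentials are 1–2 dimensional by construction;
  nothing in the WHAM/basin code assumes that, but watershed basin
  detection is implemented for 1D/2D grids only.
* Alternate-location handling keeps the highest-occupancy conformer and
  insertion codes are treated as distinct residues with a warning;
  mmCIF, hydrogens beyond the amide, and missing-loop modelling are out
  of scope.
* The dihedral-correlation pairing convention and the theta vertex are
  documented choices where the source is silent; both are isolated
  behind `CVDefinition`, so alternative conventions are one constructor
  away.
* HILLS logs and CV trajectories are plain text/CSV; no binary trajectory
  formats are read or written.
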