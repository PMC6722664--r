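---
title: "Square-well ensemble docking: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Square-well ensemble docking: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdock)
```

## Scope and intent

`swdock` estimates which members of a conformational ensemble associate
most favourably and through which residues, using rigid-body docking
with a deliberately discrete cost function. The method trades force-field
realism for speed and statistical coverage: thousands of docking runs
over randomly paired conformers give distributions — of binding energy,
of interface contacts, of per-residue interaction probability — rather
than a single "best pose". It is an exploratory, hypothesis-generating
tool (e.g. nominating aggregation hot-spot residues for mutagenesis),
not a structure predictor: rigid units cannot capture induced fit, and
the square wells have no angular terms.

## The interaction model

All energies are in h-bond units (one hydrogen bond = 1, calibrated to
`e_hb_kcal = 3` kcal/mol). Three piecewise-constant pair potentials act
between intermolecular heavy atoms; a pair contributes through every
potential for which both atoms qualify, and the total interface energy
is the unconditional sum over pairs and potentials.

**Hydrogen bond.** Donor–acceptor pairs with D, A ∈ {N, O, S}. Distance
is the only criterion: there is no consensus angular definition, bent
hydrogen bonds exist, and a distance-only well keeps evaluation cheap.
The well spans [σ, 3.2 Å) at depth −1, where σ is the sum of the two vdW
radii; 3.2 Å is the upper distance for a moderately stable hydrogen
bond. Donors are identified by a covalently bonded hydrogen (nearest
heavy atom within 1.25 Å — robust for standard geometries without a
topology file); acceptors are all O and S plus template-listed nitrogens
(His imidazole). Input structures must therefore contain hydrogens;
hydrogen-free structures are rejected loudly rather than silently
re-interpreted (a template fallback exists behind
`require_hydrogens = FALSE`).

**Electrostatics.** A double square well between formally charged
atoms: magnitude `e_el1 = 1.2/3 = 0.4` for σ < r < 1.4σ (the median
free-energy gain of a surface salt bridge normalized to the h-bond) and
`e_el2 = 0.3 × e_el1 = 0.12` for 1.4σ ≤ r < 2.3σ; sign follows the
charge product. Charge signs are restricted to the atoms of ionized
moieties (guanidinium nitrogens, Lys NZ, His imidazole nitrogens when
protonated, carboxylate oxygens, the termini) via a packaged template:
between formal charges the double well has a clear physical reading,
whereas signing every partial charge would flood the sum with weak
ill-calibrated terms. Protonation is pH-dependent: bases (His, Lys, Arg,
N-terminus) are +1 when pH < pKa, acids (Asp, Glu, Cys, C-terminus) −1
when pH > pKa, with per-residue pKa values supplied by the user (e.g.
from constant-pH simulations) and textbook defaults otherwise.

**Hydropathy.** Side-chain heavy atoms are typed into {C, N/O, N⁺, O⁻,
S} with per-atom values HP_t = −s_t·SASA_t/n_t normalized by the h-bond
energy; s_t are the atomic solvation parameters (18, −7, −34, −20,
18 cal Å⁻² mol⁻¹) and n_t = 2 estimates the neighbour count. Two atoms
of the same class within 160% of their summed vdW radii contribute
HP_i + HP_j. Mixed hydrophobic–hydrophilic pairs are excluded by default
(a conservative reading of like-class pairing; the signed-sum variant is
available via `mixed_hydropathy = TRUE`). The reference areas SASA_t are
not uniquely determined by the model's constraints; the packaged table
(C 36, N/O 90, N⁺ 20, O⁻ 33, S 40 Å²) is of the order of side-chain
atomic exposures and is calibrated once so that every normalized |HP_t|
lies inside the required 0.1–0.4 band (packaged values 0.105–0.120).
Both tables are plain configuration on `energy_parameters()`.

**Hard core and clashes.** Any intermolecular heavy-atom pair with
r < σ is a clash. Hydrogens are excluded from *all* intermolecular
terms, including the hard core, and serve only to identify donors: with
an H–acceptor hard core every well-formed hydrogen bond (D–A ≈ 3.0 Å
puts the bridging H ≈ 2.0 Å from the acceptor) would be penalized as a
clash and the h-bond term would cancel itself.

**Interval conventions.** Wells are half-open, [lower, upper): the
h-bond well includes σ, the electrostatic first well starts strictly
above σ. Boundaries are measure-zero, so only consistency and
documentation matter. A "contact" is a pair inside at least one well
(r ≥ σ); clashes are counted separately.

## The search

The docking protocol fixes one unit's centre at the origin and moves
the other along a random docking axis. `mc_dock()` implements Metropolis
simulated annealing on the objective F = U + `clash_weight` × n_clashes
(default weight 1 h-bond unit per overlapping pair): the discrete
"minimum clashes, minimal energy" optimization is folded into one scalar
so standard Metropolis applies. Moves are, with probability ½, a
rotation by an angle uniform in (0, `rot_max`] about a random axis, and
otherwise a translation of length uniform in (0, `trans_max`] along the
instantaneous centre–centre line. Rotations are split evenly between
*spins* (about the mobile centre) and *orbits* (rigid rotations about
the origin, which re-orient the docking axis). The orbit component is a
deliberate design choice: with spins only, the axis direction chosen at
initialization is invariant for the whole run, and on small test systems
the axis-constrained landscape provably cannot reach the global minimum
for a substantial fraction of random axes — a search-space defect, not a
search failure. With orbit moves the chain is ergodic over poses while
translations remain axis moves.

Defaults: 5×10⁴ steps, geometric cooling T = 2.0 → 0.05 h-bond units,
`rot_max` 15°, `trans_max` 1.5 Å, all on `dock_schedule()`. The
temperature scale is set by the well depths (order 0.1–1): T_start = 2
accepts most moves, T_end = 0.05 freezes single-well differences. The
best pose visited (not the last) is returned, matching the "optimized
complex" semantics, and its recorded binding energy is always the pure
interface energy re-evaluated at that pose. The walk is confined to
centre separations between 0.5 Å and the sum of bounding radii plus the
largest pair cutoff: beyond that shell the objective is identically
zero, so the bound discards no minima and prevents unbounded outward
diffusion. Initial placement (sum of bounding radii + 2 Å along a random
axis, uniform random orientation) is guaranteed contact- and clash-free.

`ensemble_dock()` draws conformer pairs uniformly with replacement,
docks each under a per-run seed taken from a counter-based stream
derived from the master seed (results do not depend on execution
order), and stops when the running mean and standard deviation of the
binding energy have both moved by less than `tol` × (current sd) over
the last `window` additions — defaults `tol = 0.02`, `window = 50`,
production target 1000–1500 dimers (or 1000 tetramers; tetramer mode is
the same call with dimers re-read as rigid units). The (min, max) target
is enforced as hard bounds.

## Analysis products

- `binding_energy_density()`: Gaussian KDE with Silverman's rule
  (`bw.nrd0`) on a uniform grid spanning the sample ± 3 bandwidths; the
  mode **E_M** is the grid argmax. A KDE (rather than a histogram) gives
  a smooth, binning-free mode; the bandwidth is exposed. Zero-variance
  samples return the common value with a degenerate flag.
- `contact_probability_map()`: a residue–residue contact exists in a
  member iff at least one atom pair of those residues lies inside its
  type-specific well; multiple atom pairs count once per member, and the
  probability is the count over the full ensemble size (per-ensemble
  normalization, stated explicitly since a per-interface alternative is
  conceivable). Residues are labelled `chain:resno` in author numbering.
- `hotspot_probabilities()`: contacts ranked by ensemble frequency (ties
  broken by frequency descending, then residue identifiers ascending),
  the top 50 retained (all, if fewer), and each residue scored by the
  probability — over members, a single clear sample space — of
  participating in at least one subset contact. The alternative
  averaging over subset contacts is available via `per_contact = TRUE`.
- `representative_conformer()`: the member with binding energy nearest
  E_M; exact ties resolve to the lowest member index.

## The synthetic-structure generator

`make_toy_unit()` builds deterministic all-atom units from idealized
residue templates (10 residue types, hydrogens included, bond lengths
tracking standard values) arranged either as an extended rod with side
chains radiating at the golden angle or as a compact spherical shell
("blob") with side chains pointing outward. It emulates what the method
actually consumes — typed atoms with realistic radii, donors, charges
and hydropathy classes at plausible densities and a clash-free core —
and deliberately not real protein stereochemistry: no rotamer libraries,
no secondary structure, no chain continuity in blob mode, and no
conformational heterogeneity beyond the seed. Tests passing on these
fixtures therefore validate the energy model, the search and the
statistics, but say nothing about biological accuracy on real conformer
ensembles, which remain the user's input. `make_planted_ensemble()`
generates stub ensembles with a known sticky residue (planted contact at
rate 0.8 vs background 0.1 over 30 background pairs) so hot-spot
recovery has a ground truth by construction.

## Verification strategy and problem sizes

Every layer has an independent oracle: the cell-list C++ interface
energy is checked to 1e-9 against a pure-R all-pairs double loop
(100 randomized pairs); the annealer against an exhaustive 6-DOF
grid search (`grid_search_dock`, 0.5 Å / 45° on 2-atom systems whose
analytic optimum is one h-bond, −1) with a ≥ 90%-of-seeds success bound;
hot-spot ranking against planted ground truth (rank 1 in ≥ 95% of 40
seeds); the KDE mode against a 700/300 bimodal synthetic sample (±0.5 of
the dominant component). The test suite docks small units (4–10
residues, 200–20 000 steps) and one 50-residue pair to a converged
ensemble (≤ 100 members, 5000 steps, tol 0.05, window 30) — sizes chosen
so the whole suite runs in minutes while still exercising the production
code paths; production-scale parameters are the defaults documented
above. Reproducibility is bit-exact: (master seed, inputs, parameters)
determines every pose, energy and output file byte-for-byte.

## Known limitations

- Rigid bodies: no induced fit, side-chain repacking or relaxation; any
  force-field refinement of output ensembles is an external
  post-processing step.
- The electrostatic term ignores partial charges and screening; the
  hydropathy term double-counts nothing but is blind to curvature and
  burial context.
- pKa values are inputs, not predictions; coupling between protonation
  and binding is not modelled.
- E_M values are comparable across ensembles run with the same
  parameter set, but are not absolute binding free energies.
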