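# swdock — square-well Monte Carlo ensemble docking

`swdock` is an R package for rigid-body protein–protein docking with a
piecewise-constant (square-well) interaction model, aimed at studying
**protein association and aggregation propensity** from conformational
ensembles: which conformers dimerize most favourably, through which
interface, and which residues act as association **hot-spots**. It was
built with amyloidogenic systems in mind (e.g. β2-microglobulin variants,
whose pH-dependent intermediates dimerize through specific adhesion
loops), but it runs on any all-atom PDB conformers that include
hydrogens.

## The model

Two rigid all-atom units interact through three square-well pair
potentials, summed over every intermolecular heavy-atom pair *(i, j)*:

```
U = Σ_ij  U_ij^H  +  U_ij^EL  +  U_ij^HP
```

All energies are in **h-bond units**: one hydrogen bond has depth 1,
calibrated to 3 kcal/mol.

- **Hydrogen bond** `U^H`: donor–acceptor pairs (D, A ∈ {N, O, S};
  donors identified by a covalently bonded hydrogen). Depth −1 between
  the hard-core distance σ (the sum of the two van der Waals radii) and
  the 3.2 Å cutoff; zero beyond.
- **Electrostatics** `U^EL`: a double square well between formally
  charged atoms. Magnitude 0.4 for σ < r < 1.4σ (the 1.2 kcal/mol
  surface salt-bridge free energy over the 3 kcal/mol h-bond), and
  0.3 × 0.4 = 0.12 for 1.4σ ≤ r < 2.3σ; repulsive between like charges,
  attractive between opposite ones. Charges are assigned **per pH** from
  a pKa table (His/Lys/Arg/N-terminus positive below their pKa,
  Asp/Glu/Cys/C-terminus negative above).
- **Hydropathy** `U^HP`: side-chain heavy atoms are typed into
  {C, N/O, N⁺, O⁻, S} with per-atom values HP_t = −s_t·SASA_t / n_t
  (atomic solvation parameters s_t of 18, −7, −34, −20, 18 cal Å⁻² mol⁻¹,
  normalized to h-bond units; all |HP_t| within 0.1–0.4). Two atoms of
  the same hydropathy class closer than 160% of their summed vdW radii
  contribute HP_i + HP_j — attractive for hydrophobic pairs, repulsive
  for hydrophilic ones.

Pairs closer than σ are **clashes**; the Monte Carlo objective is
`F = U + clash_weight × n_clashes`.

**MC-ED (Monte Carlo ensemble docking):** one unit is fixed at the
origin; the mobile unit starts at a random orientation on a random
docking axis and performs Metropolis simulated annealing over rotations
and translations along the instantaneous axis. Each run keeps its best
pose. Runs over randomly drawn conformer pairs accumulate until the mean
and standard deviation of the binding energy converge (production
ensembles of 1000–1500 dimers; tetramers are the same call with dimer
pools re-read as rigid units). The analysis layer computes the
binding-energy probability density and its mode **E_M**, residue–residue
**intermolecular probability maps** (IPMs), **hot-spot** probabilities
over the 50 most frequent contacts, and a representative conformer at
the mode.

## Worked example

Dock two synthetic 20-residue monomers at pH 5.2 and rank the hot-spots:

```r
library(swdock)

params <- energy_parameters()
pm     <- protonation_model(pH = 5.2, pka = c("A:3" = 6.5))

mono1 <- make_toy_unit(fixture_spec(20, geometry = "blob", seed = 1), "mono1")
mono2 <- make_toy_unit(fixture_spec(20, geometry = "blob", seed = 2), "mono2",
                       chain = "B")
mono1 <- classify_atoms(assign_protonation(assign_radii(mono1), pm), params)
mono2 <- classify_atoms(assign_protonation(assign_radii(mono2), pm), params)

ens <- ensemble_dock(list(mono1), list(mono2), params,
                     dock_schedule(n_steps = 10000),
                     target = c(30, 60), tol = 0.05, window = 20,
                     rng_seed = 42, pH = 5.2)
summary(ens)
#> Ensemble of 44 docked complexes (converged)
#>   U: mean -7.151, sd 1.658, range [-11.608, -4.248]
#>   mean contacts 29.2, mean clashes 0.2

d <- binding_energy_density(ens)
d
#> <sw_density> n = 44, E_M = -6.220 h-bond units (bw 0.700)

head(hotspot_probabilities(ens, subset_size = 50)$table, 3)
#>   residue   unit probability rank
#> 1     A:5  fixed   0.2954545    1
#> 2    B:13 mobile   0.2954545    2
#> 3     A:2  fixed   0.2727273    3
```

The ensemble converged at 44 members: the running mean and spread of the
binding energy stabilized. The most likely binding energy of a dimer is
E_M ≈ −6.2 h-bond units (≈ −18.7 kcal/mol at the 3 kcal/mol
calibration); residue 5 of the fixed monomer participates in the most
frequent intermolecular contacts in ~30% of the dimers, making it the
top dimerization hot-spot of this toy ensemble. `write_ensemble()` saves
the ensemble as a multi-model PDB (binding energies in REMARK lines);
`contact_probability_map()` gives the full residue–residue IPM.

For real systems replace the toy units with PDB conformers:
`prepare_structure("conformer.pdb", protonation_model(7.2))` — one call
per conformer, any number of conformers per pool. A thin command-line
wrapper with `fixtures`, `dock` and `analyze` subcommands is installed
at `inst/scripts/swdock.R`.

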