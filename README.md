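# tmdpath

Targeted molecular dynamics (TMD) and transition-pathway analysis for
two-state proteins, at desk scale.

Metamorphic proteins such as the spindle-checkpoint protein Mad2 adopt two
distinct native folds — an open and a closed state — and their biological
activity hinges on the transition between them. Characterising that
transition computationally takes three ingredients: a way to *drive* a
simulation from one known end-state structure to the other, a physics
engine the drive can act on, and a post-processing suite that turns the
resulting trajectory into interpretable structural observables. `tmdpath`
packages all three for R users: the driving scheme is the standard TMD
restraint, the engine is a coarse-grained dual-basin structure-based model
(one bead per residue) that makes the workflow tractable on a laptop, and
the analysis suite mirrors what an MD practitioner would run on an all-atom
trajectory — RMSD series, dynamical cross-correlation matrices (DCCM),
hydrogen-bond occupancies, hydrophobic contacts, segment mass-center
distances, pocket volumes and correlated-segment networks.

It is intended for structural bioinformaticians and molecular modellers who
want a transparent, fully scriptable implementation of the TMD workflow for
method development, teaching, or prototyping analyses before committing to
all-atom engines.

## The methods

**TMD restraint.** A harmonic energy on the deviation between the current
mass-weighted best-fit RMSD to the target structure and a prescribed target
value that decays linearly in time:

```
E_TMD = (1/2) k N [ RMSD(t) − RMSD₀(t) ]²
```

with `k` the per-atom force constant (kcal mol⁻¹ Å⁻²) and `N` the number of
restrained atoms. Forces use the analytic gradient of the best-fit RMSD
(rotational terms vanish at the Kabsch optimum):
`∂RMSD/∂xᵢ = wᵢ (xᵢ − ŷᵢ) / (RMSD · Σw)`, where `ŷ` is the target after
optimal superposition onto the current frame.

**Dual-basin model.** Each end state defines a structure-based (Gō-like)
basin — harmonic bonds, harmonic native-contact tethers, soft-core
repulsion — and the two are blended with a log-sum-exp soft minimum,
`V = −(1/β) ln(e^{−βV_open} + e^{−βV_closed})`, so both references are
genuine local minima and a driven trajectory crosses smoothly between them.
Dynamics are BAOAB Langevin with a linear heating ramp, equilibration and
production phases; a staged minimization ladder (positional restraints
100 → 75 → 50 → 25 → 0 kcal mol⁻¹ Å⁻²) prepares the start.

**DCCM.** `C(i,j) = ⟨Δrᵢ·Δrⱼ⟩ / [⟨|Δrᵢ|²⟩⟨|Δrⱼ|²⟩]^{1/2}` over per-residue
displacement vectors, after optional superposition of every frame onto the
mean structure. Segment-level correlation networks count residue pairs with
`|C| ≥ c` between annotated segments.

**Pockets.** Grid flood-fill with a 1.4 Å probe (LIGSITE/POCKET family):
cavities are probe-accessible connected components not reachable from the
box boundary; volume is voxel count × spacing³.

## Worked example

```r
library(tmdpath)

toy <- make_two_state_toy(n_residues = 60, seed = 1)
toy
#> ToySystem: 60 residues, seed 1
#>   open vs closed backbone RMSD: 6.30 A

model <- build_dual_basin(toy$open, toy$closed)
model
#> DualBasinModel: 60 beads
#>   native contacts: open 171 / closed 196
#>   k_bond 100, k_contact 1.1, k_rep 2 kcal/(mol A^2); cutoff 8 A; beta_mix 0.025

traj <- run_tmd(model, toy$open, toy$closed, k = 0.5,
                protocol = sim_protocol(), seed = 1)
rmsd(traj$frames[[n_frames(traj)]], coords(toy$closed),
     weights = toy$closed$atoms$mass)
#> [1] 0.8679745
```

The driven run takes the open conformer (terminal strand packed on the
sheet edge) to the closed conformer (strand folded across the sheet face),
6.3 Å away in backbone RMSD, and lands within 0.87 Å of the target — the
transition "converged" by the usual < 2 Å criterion. The run log records
the schedule: by the final frame the prescribed target RMSD (`RMSD0`) has
decayed to zero while the restraint energy `E_TMD` absorbs the residual
thermal deviation.

The correlated-segment network of the transition trajectory then traces
which parts of the chain move together:

```r
net <- build_segment_network(compute_dccm(traj), toy$segments,
                             threshold = 0.5)
path_exists(net, "β1 toy", "β7/8 toy")
#> [1] "β1 toy"   "β7/8 toy"
```

Here the relocating terminal segment (the β7/8 analog) is directly and
strongly coupled to the N-terminal strand analog (155 threshold-passing
residue pairs link it to the αA analog alone) — the driven rearrangement
moves the whole sheet face in a concerted way.

Real end-state structures can be used in place of the toy: read two
index-matched conformers with `read_pdb()`, annotate segments with
`default_segments()` (packaged tables for both Mad2 folds) or
`read_segments()`, and run the same functions. The staged workflow —
equilibrate, force-constant scan, bidirectional TMD, intermediate
extraction, full analysis — is available as `run_pipeline()` and as
subcommands of `inst/scripts/tmdpath-cli.R`.

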