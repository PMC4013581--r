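---
title: "Driving and analysing two-state protein transitions with tmdpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driving and analysing two-state protein transitions with tmdpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdpath)
```

`tmdpath` implements a complete desk-scale workflow for studying the
conformational transition of a protein between two known end-state
structures: a targeted-molecular-dynamics (TMD) biasing scheme, a
coarse-grained physics engine for it to act on, and the post-trajectory
analysis suite a practitioner would apply to the resulting path. This
vignette is the package's own account of the underlying models, the
parameters that matter, the synthetic systems used for validation, and the
design decisions taken where the method leaves room.

## The TMD restraint

TMD steers a simulation between two conformations by adding a harmonic
energy on a single collective coordinate — the mass-weighted best-fit RMSD
to the target structure:

$$E_\mathrm{TMD}(t) = \tfrac12\, k\, N\, \big[\mathrm{RMSD}(t) -
\mathrm{RMSD}_0(t)\big]^2,$$

where $k$ is the per-atom force constant in kcal mol$^{-1}$ Å$^{-2}$, $N$
the number of restrained atoms, and $\mathrm{RMSD}_0(t)$ a prescribed
target value that decreases linearly in time, dragging the system toward
the target. Because the restraint acts on one collective coordinate, the
individual atoms remain free to rearrange around the constraint — the
mechanism of the transition is an outcome, not an input.

Forces require $\partial\,\mathrm{RMSD}/\partial x_i$. At the optimal
(Kabsch) superposition the derivatives through the fitted rotation and
translation vanish (an envelope-theorem argument), leaving the closed form

$$\frac{\partial\,\mathrm{RMSD}}{\partial x_i}
 = \frac{w_i\,(x_i - \hat y_i)}{\mathrm{RMSD}\cdot\sum_j w_j},$$

with $\hat y$ the target rotated into the current frame. The gradient is
clamped to zero below an RMSD of $10^{-6}$ Å: the RMSD is not
differentiable at zero, and the schedule ends there, so the clamp
guarantees finite forces at the end of a run. Both the gradient and the
dual-basin forces are validated against central finite differences in the
test suite.

Scheduling choices:

* the run's heating and equilibration phases are unrestrained; the
  schedule's start value anchors to the *actual* RMSD at the start of
  production, so the restraint switches on unstrained;
* the target RMSD decays to zero over the first 80% of production
  (`schedule_frac`) and holds at zero for the remainder — a short settling
  period at the target, mirroring the usual transition-then-equilibrate
  protocol;
* after the schedule ends the target value holds, so restarted or extended
  runs remain well-defined.

## The dual-basin engine

The full-scale version of this workflow runs on an all-atom, explicitly
solvated force field. That engine is replaced here by a coarse-grained
dual-basin structure-based model: one bead per residue at the Cα position
with the average residue mass (110 Da), and a potential with a basin
engineered at each end-state reference:

$$V_b = \sum_\mathrm{bonds} k_\mathrm{b}(r - r^0_b)^2
      + \sum_\mathrm{contacts} k_\mathrm{c}(r - r^0_b)^2
      + \sum_{\mathrm{non\text{-}native},\, r<\sigma} k_\mathrm{r}(\sigma - r)^2$$

Native contacts of basin $b$ are the pairs at least two positions apart
along the chain that sit within the contact cutoff in reference $b$; all
other nonbonded pairs feel only soft-core repulsion inside the excluded
radius $\sigma$. The two basins combine by a log-sum-exp soft minimum,

$$V = -\tfrac{1}{\beta_\mathrm{mix}}
 \ln\!\big(e^{-\beta_\mathrm{mix} V_\mathrm{open}}
         + e^{-\beta_\mathrm{mix} V_\mathrm{closed}}\big),$$

which can lower the energy below the lower basin by at most
$\ln 2/\beta_\mathrm{mix}$ and leaves both references as local minima.
Forces blend with the softmax weights of the two basins.

Defaults and the reasoning behind them (all config-exposed):

| parameter | default | units | why |
|---|---|---|---|
| `k_bond` | 100 | kcal mol⁻¹ Å⁻² | stiff virtual Cα–Cα bonds; period ≈ 0.23 ps, resolved by the 10 fs step |
| `k_contact` | 1.1 | kcal mol⁻¹ Å⁻² | native wells a few $k_BT$ deep per contact at 300 K: stable basins that a $k\!=\!0.5$ restraint can still unseat |
| `k_rep` | 2 | kcal mol⁻¹ Å⁻² | firm but not impenetrable excluded volume, so strands can slide past each other under drive |
| `contact_cutoff` | 8 | Å | standard Cα Gō-model range; captures cross-strand neighbours (≈ 6.6 Å) and their diagonals (≈ 7.6 Å) |
| `excluded_radius` σ | 3.8 | Å | just below the 4.0 Å clash floor the generators guarantee, so reference states feel no repulsion |
| `beta_mix` | 0.025 | (kcal/mol)⁻¹ | soft enough that the inter-basin barrier is crossable under modest bias, sharp enough that each reference feels only its own basin (residual force < 10⁻³ kcal mol⁻¹ Å⁻¹) |

`beta_mix` is the one genuinely two-sided dial: sharper mixing deepens the
effective barrier between basins (at 0.03 and above the reverse transition
of the toy system can stall under a 0.5 kcal mol⁻¹ Å⁻² restraint), softer
mixing lets the inactive basin leak measurable force onto the reference
structures. 0.025 sits in the window that satisfies both, with the
reference-force contract re-checked in the tests.

**Integration.** BAOAB Langevin with per-atom Maxwell–Boltzmann
initialisation. The weak-coupling constant of the original protocol
(0.2 ps) maps to Langevin friction $\gamma = 1/0.2\,\mathrm{ps}^{-1}$ —
BAOAB gives correct canonical sampling, which weak-coupling thermostats do
not. With `coupling = 0` the O-step disappears and the integrator reduces
exactly to velocity Verlet; that limit is used for the energy-conservation
test (relative drift $\le 10^{-3}$ over $10^4$ steps at a 1 fs step — the
drift is the shadow-Hamiltonian oscillation and scales as $\mathrm{d}t^2$).
The default production step of 10 fs is checked against the stiffest mode
at startup. Units follow the AKMA-style convention: Å, ps, Da, kcal/mol,
with acceleration = force/mass × 418.4 Å ps⁻².

**Protocol.** The staged preparation mirrors an explicit-solvent setup at
desk scale: a minimization ladder with positional restraints
100 → 75 → 50 → 25 kcal mol⁻¹ Å⁻² followed by an unrestrained stage
(steepest descent with backtracking; the stage energies are returned for
bookkeeping), linear heating 0 → 300 K over 10 ps, 10 ps equilibration,
then 200 ps production (20 000 steps; the TMD schedule spans the first 80%
= 16 000 steps). Constant-pressure equilibration from the solvated
protocol is dropped — a vacuum coarse-grained model has no box — and there
are no hydrogens, so bond constraints are moot.

## The two-state toy system

`make_two_state_toy()` generates the packaged study system: a 60-residue
chain with exact 3.8 Å virtual bonds whose core (three strands joined by
tight turns, a serpentine sheet) is *identical* in both states, while the
terminal segment relocates completely — packed against the outer edge of
the last strand in the open state, folded through an out-of-plane turn
into the groove across the sheet face in the closed state. Every tail
contact partner changes between states; the backbone RMSD between the
conformers is 6.3 Å. The seed perturbs the step directions slightly
(renormalised, so bond lengths stay exact) and the same perturbation is
shared by both conformers, keeping the core superimposable. The generator
asserts its own contract — bonds 3.8 ± 0.01 Å, nonbonded beads ≥ 4.0 Å,
state separation ≥ 6 Å — and fails loudly rather than emit a degenerate
system.

What the toy emulates: a two-state fold with a genuine tertiary contact
network, a large-amplitude strand-relocation transition, and segment
analogs (β1, αA, αC, β6/4/5, β5–αC loop, β7/8) for the distance and
network analyses. What it does not emulate: side chains, sequence
heterogeneity, hydrogen-bond geometry (bead models have no hydrogens),
solvent friction anisotropy, or realistic local backbone statistics.
Passing tests on the toy therefore validate the *machinery* — restraint
mechanics, integrator correctness, analysis algebra — not any biological
claim about a real protein.

Under the default conditions the TMD behaviour reproduces the qualitative
shape of a force-constant scan: mean final RMSD to target across five
seeds decreases monotonically over $k \in \{0.2, 0.5, 0.8, 1.0\}$
(≈ 1.8 / 0.83 / 0.65 / 0.63 Å), and both transition directions converge
below 2 Å at $k = 0.5$. One property is worth stating precisely: the
restraint's tracking error $|\mathrm{RMSD}(t)-\mathrm{RMSD}_0(t)|$ stays
within 1 Å throughout the schedule for $k \ge 0.8$, while at $k = 0.5$ the
transient excursion at the basin crossing reaches 0.9–1.3 Å depending on
seed — the combination of friction drag on the relocating segment and the
300 K thermal floor at that restraint stiffness. The tests assert the 1 Å
width at $k = 1$ and a 1.5 Å bound at $k = 0.5$.

## Analyses

**RMSD series** use mass-weighted Kabsch superposition per frame (the
reflection branch is corrected, so rotations are always proper). Whether
published RMSD curves are mass-weighted or uniform is often unstated; both
weightings are exposed, mass-weighted is the default, matching the
restraint definition.

**DCCM.** $C(i,j) = \langle \Delta r_i \cdot \Delta r_j\rangle /
[\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle]^{1/2}$ with
$\Delta r_i(t) = r_i(t) - \langle r_i\rangle$. The product in the
numerator is the vector dot product — the only reading that yields a
scalar in $[-1,1]$. With `fit = TRUE` (default) every frame is first
superposed onto the mean structure and the mean/fit cycle is iterated
once; the fit flag is recorded in the result. Two numerical notes:
zero-variance sites are masked as `NA` with a warning, never silently
zeroed; and rigid-body fitting removes six degrees of freedom, which
biases entries by $O(1/n)$ — with 200 frames, individual entries also
carry sampling noise of order $1/\sqrt{3F} \approx 0.04$, so the
"no spurious correlation" property is tested as a *difference* against the
same noise realisation without rigid motion, not as an absolute bound.

**Hydrogen-bond occupancy** = percentage of frames satisfying both
geometric criteria, rounded to one decimal. The criteria are
config-exposed (`hbond_criteria()`) with the common trajectory-analysis
defaults: donor–acceptor heavy-atom distance ≤ 3.5 Å and donor–H–acceptor
angle ≥ 120°. Published occupancy tables rarely state their convention;
exposing the criteria makes any convention reproducible. Donor/acceptor
rows are matched by residue + atom name, any hydrogen on the donor residue
may complete the bond, and pairs whose donor has no hydrogen are skipped
with a warning rather than silently reported as 0%.

**Hydrophobic contacts** use the strict carbon–carbon `distance < 4.5 Å`
definition (4.49 Å is a contact; 4.50 Å is not), reported as per-frame
minimum distances plus boolean flags. In bead models the beads stand in
for the carbons — a documented semantic shift, since a bead–bead distance
aggregates a whole residue.

**Segment mass-center distances** are internal coordinates (no
superposition), computed from mass-weighted centroids of the annotated
segments. The packaged segment tables for the two Mad2 folds follow the
published element ranges; two details needed decisions: the β5–αC loop has
no published range and is defined as the inter-element gap 106–121 (forced
by the flanking elements: β5 ends at 105, αC starts at 122), and the
closed-state table has no β1 entry because the closed fold absorbs the
N-terminal strand into the extended αA helix (12–37).

**Pockets.** A CASTp-style weighted-Delaunay computation is replaced by a
grid flood-fill of the LIGSITE/POCKET family: voxels inside an atom's
element radius (Bondi-style: C 1.70, N 1.55, O 1.52, S 1.80 Å; bead 3.4 Å)
are protein; voxels whose centre is within the probe radius (1.4 Å
default) of any atom surface cannot host the probe; solvent is
flood-filled from the box boundary through probe-accessible space
(6-connected sweeps — a diagonal-only channel is physically inaccessible
to a finite probe); cavities are the remaining probe-accessible components
(26-connected), ranked by volume. Volume is voxel count × spacing³, area
is exposed-face count × spacing², lining residues are atoms whose surface
comes within probe + one voxel of the component. Two definitional points:
the reported volume counts the probe-*centre*-accessible region (the
convention that matches the analytic hollow-sphere value
$\tfrac43\pi(R - r_\mathrm{atom} - r_\mathrm{probe})^3$ used as the test
oracle), and the analytic comparison needs a dense shell — a 150-atom
shell of radius 8 Å measures within 6% of the continuum value, whereas a
sparse 60-atom shell genuinely reads ~17% high because the accessible
region bulges into the angular gaps between atoms (a property of the
fixture, not a grid artefact; the measurement is grid-converged to < 0.2%
under spacing halving). The box margin is $3(r_\mathrm{probe} +
r_\mathrm{max})$ so boundary flood-fill always starts in bulk solvent.
Matching "topologically equivalent" pockets across conformers is exposed
as a lining-residue Jaccard utility (`match_pockets()`), an interpretation
rather than an asserted method.

**Segment networks.** An inter-residue edge exists where $|C(i,j)| \ge c$;
the weight of a segment-pair edge is the *count* of such residue pairs, so
drawn line widths are proportional to the sum of connecting edges. The
magnitude $|C|$ is used because published correlated-segment figures do
not distinguish sign; signed sub-networks are available. The default
threshold $c = 0.5$ is a choice (no published value exists) and is
recorded in every output. Path queries return the shortest hop-count path,
ties broken by the larger minimum edge weight and then lexicographically —
a deterministic, documented tie-break rather than an arbitrary one.

## The pipeline

`run_pipeline()` chains the full procedure: toy generation (or end-state
input), staged minimization and unbiased equilibration of both states, a
TMD force-constant scan over {0.2, 0.5, 0.8, 1.0} kcal mol⁻¹ Å⁻²
(selection rule: smallest k with final RMSD < 2 Å), bidirectional TMD,
extraction of intermediate conformations at fractions 0.35 / 0.65 / 0.95
of the schedule (mapping the ~3.5 / 6.5 / 9.5 ns extraction points of a
10 ns schedule), short unbiased re-equilibration of each intermediate, and
the full analysis battery. Intermediate "time-average structures" are the
mean of post-burn-in frames after superposition onto the final frame —
mean coordinates can contract geometry slightly, so the averaging choice
is recorded in output metadata rather than asserted as canonical. Every
output lands under a run directory keyed by a hash of the configuration;
completed stages are marked and skipped on rerun, and an identical
configuration reproduces numeric tables byte-for-byte. Hydrogen-bond
occupancy is toggled off in the default coarse-grained pipeline (no
hydrogens exist); it activates for all-atom inputs.

## Problem sizes and runtimes

The packaged study conditions are a 60-residue toy, 20 000 production
steps of 10 fs (200 ps) with the TMD schedule over the first 16 000 steps
— within the 10⁴–10⁵ step design range for the coarse-grained schedule. A
single TMD run takes ~20 s on one core; the full four-constant, five-seed
scan used in the monotonicity check runs in ~6 minutes. Pocket
measurements on the validation shell take ~0.3 s at 0.5 Å spacing and
~2 s at 0.25 Å.

## Known limitations

* The engine is a vacuum coarse-grained model: no solvent, electrostatics,
  side chains, or hydrogens. Quantities that depend on those (real
  occupancy tables, absolute pocket sizes of real proteins, kinetics) are
  out of reach by design; the package validates machinery and produces
  qualitative transition phenomenology.
* The dual-basin surface is phenomenological. Barrier heights are set by
  `beta_mix` and the contact stiffness, not by any physical free-energy
  estimate, and the workable `beta_mix` window is finite (see above).
* Harmonic native contacts never break permanently; the soft-minimum
  blending is what allows basin exchange. Systems whose transition
  requires locally unfolding a region held by *both* basins will resist
  the drive.
* TMD itself finds *a* path consistent with the bias, not the minimum
  free-energy path; at low `k` the path can differ from run to run, which
  is why the force-constant scan and the bidirectionality check are part
  of the workflow.
* Atom correspondence between end states is positional (index-matched);
  no sequence alignment is performed.
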