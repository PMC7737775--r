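---
title: "Rigid-body ensemble modeling and ensemble analysis with semiflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body ensemble modeling and ensemble analysis with semiflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiflex)
```

## The modeling problem

Many proteins and protein–RNA complexes are *semistructured*: well-folded
domains connected by flexible peptide or RNA linkers, so that no single
conformer describes the molecule. Pulsed EPR experiments (DEER/PELDOR) on
pairs of spin labels deliver *distance distribution restraints* (DDRs):
not just a mean distance but the full probability distribution of a
nanometer-range distance, which carries information about the *width* of
the conformational ensemble. semiflex models such systems as distributed
arrangements of rigid bodies joined by flexible linkers, fits conformer
populations against DDRs and small-angle scattering (SAS) curves, and
provides analytics for detecting weak order and weak disorder in the
resulting ensembles.

The pipeline has four stages, each usable on its own:

1. **Arrangement generation** (`run_rigi()`): enumerate distance matrices
   compatible with the DDRs, embed them by distance geometry, test and
   refine the resulting rigid-body arrangements (RBAs).
2. **Linker construction** (`link_ensemble()`): grow coarse-grained
   peptide/RNA linkers between anchor points on the placed bodies;
   arrangements whose linkers cannot be built are discarded.
3. **Population fitting** (`block_fit()`): fit conformer populations
   against restraint subsets, balance subsets through a loss of merit,
   and prune negligible conformers block by block.
4. **Ensemble analysis**: ensemble width (`ensemble_width()`), residue
   pair correlation (`pair_correlation()`), and local compaction with
   global Flory fits (`flory_fit()`, `compaction_matrices()`).

## Arrangement generation by enumerated distance sampling

Each rigid body carries exactly three *reference sites*, chosen by
`choose_reference_sites()` as the largest, most nearly equilateral
triangle over the candidate sites (maximize the minimum side length; break
ties by area). For `n` bodies the `9n(n-1)/2` inter-body reference
distances over-determine the `6(n-1)` rotation/translation parameters, so
an ensemble of arrangements can be generated by sampling *distances*
rather than poses.

A Gaussian restraint with mean `m` and width `s` is sampled on the
interval `[m - s, m + s]`; undetermined pairs default to bounds of 5 and
180 Å. Triangle-inequality smoothing (`smooth_bounds()`) tightens all
bounds before sampling; infeasible bound sets are reported as such rather
than silently truncated. `plan_sampling()` places `s_i =
ceiling(width_i/dr) + 1` equidistant samples (endpoints included) on each
restrained interval, choosing the smallest resolution `dr` on a 0.01 Å
grid such that the total trial count `T = prod(s_i)` stays within the
user's cap `T_max`. Only explicitly restrained pairs are enumerated;
undetermined pairs are fixed at the midpoint of their smoothed bounds.
Enumerating a default 175 Å-wide interval would make `T` astronomically
large without adding information, and the trial-count arithmetic of
realistic runs shows that only restrained pairs carry more than one
sample.

Each of the `T` complete distance matrices is embedded into 3D by the
classical metric-matrix method (double-centered squared distances, top-3
eigendecomposition). A matrix is rejected as non-embeddable when its
negative eigenvalue mass exceeds 1% of the positive mass. Distances
cannot distinguish mirror images, so *both enantiomorphs* are emitted and
tested independently; downstream restraints, clash tests and linkers
discriminate between them.

Candidate arrangements are tested in order of increasing cost
(`test_rba()`): auxiliary DDR intervals, peptide linker maximum extension
(3.8 Å per residue), RNA linker maximum extension (7 Å per nucleotide by
default), the crosslink fraction `f_x`, inter-body clashes (2 Å
heavy-atom cutoff by default), and finally a probability score — the
geometric mean of the Gaussian fractions
`g_i = exp(-(r_sim - m_i)^2/(2 s_i^2))` — against the threshold `p_thr`
(default 0.5; alternatively parametrized through a coverage percentage by
`coverage_to_threshold()`). Before refinement, the tests allow slack of
one sampling resolution `dr`, added to intervals and in quadrature to the
Gaussian widths: a model generated from distances sampled at resolution
`dr` may deviate by that much from a fully compliant one. Label-site
positional uncertainty is likewise added in quadrature to restraint
widths; this replaces explicit rotamer modeling of the labels, which is
out of scope.

Survivors are refined (`refine_rba()`) by derivative-free local search
over the `6(n-1)` parameters, minimizing only the summed squared
violations of the restraint intervals — now without the sampling-slack
allowance. Refinement starts from a zero displacement and **stops at the
first violation-free point**: the goal is feasibility, not optimality,
because continuing to tighten restraints would artificially narrow the
ensemble. A violation-free input is returned unchanged.

## Flexible linkers

Linkers are represented at one interaction center per residue (Cα, 3.8 Å
virtual bonds) or nucleotide (P, 5.9 Å), grown unit by unit with bend
angle and pseudo-torsion drawn from a fragment library on a 5° grid
(`make_fragment_library()`). The shipped libraries are *synthetic* —
a coil-region mixture for peptides and a single broad basin for RNA; a
loader for user libraries in a 3-column text format keeps published
libraries pluggable. Growth toward an anchor reweights candidate steps by
a Gaussian of the deviation from a uniformly shrinking target gap and
discards steps that make closure infeasible (remaining gap above the
per-unit maximum times remaining units) or that clash (3 Å coarse
cutoff). Atoms within one cutoff of the anchors are exempt from the clash
test so chains can emerge from a body's surface.

A moderate terminal miss (up to 3 Å) is repaired by `close_anchor()`,
which distributes the required axial stretch, rotation about the
anchor-anchor axis, and residual perpendicular shift uniformly over the
backbone units; bead `k` receives the fraction `(k-1)/(N-1)` of each
component, so the a-side anchor never moves. Closure fails if any bond
would stretch by more than 10%. The defaults (0.5 Å closure tolerance,
3 Å moderate-miss threshold, 10% distortion cap) are declared package
choices — the qualitative rule ("fix moderate misses by distributed
deformation") does not prescribe numbers. If any declared linker cannot
be built within its attempt and runtime limits, the whole arrangement is
discarded (`link_rba()`), and the accounting `accepted = linked +
discarded` always holds exactly.

## Population fitting and ensemble reduction

For a site pair, `predict_ddr()` predicts the ensemble distance
distribution as the population-weighted sum of per-conformer Gaussians of
width `sigma_label` (default 3 Å, the typical spin-label position
uncertainty). Agreement with an experimental distribution is the
*overlap* `o = integral of min(P_pred, P_exp)` — 1 for identical, 0 for
disjoint distributions. Distributions live on a fixed 0–200 Å grid with
0.5 Å bins by default; the grid is exposed because the overlap of two
narrow distributions carries a discretization error of order 1e-3 at
0.5 Å. The DDR subset metric is `m_DDR = 1 - (prod o_i)^(1/D)`, which
strongly penalizes any single poorly-fit restraint.

SAS curves are scored by `chi^2` with a fitted scale and additive
constant per curve, reduced by the number of `q` points; the subset
metric sums over curves. Per-conformer intensities come from a
coarse-grained Debye evaluator (`debye_predictor()`,
`I(q) = sum f_i f_j sinc(q d_ij)`, histogram-accelerated by default), and
a predictor hook accepts a function, a precomputed matrix, or per-conformer
curve files, so externally computed curves can be substituted bit-exactly.
The per-point reduced `chi^2` with fitted scale and offset is a
documented, fixed convention; published values computed under other
conventions are not directly comparable.

`fit_populations()` minimizes a subset metric over the probability
simplex via the substitution `p = w^2 / sum(w^2)` with a quasi-Newton
(BFGS) inner solver, analytic gradients, and five seeded starts by
default. With several restraint subsets it first fits each subset alone
(giving the subset optima `m1_k`), then minimizes the *loss of merit*
`L = mean(m2_k/m1_k - 1)`, where `m2_k` are the metrics of the common
population vector. Normalizing by `m1_k` weights each subset by its own
attainable quality, which absorbs systematic errors between techniques;
`L = 0` only for perfectly consistent subsets. Because `m1_k` is itself
a numerical estimate, any better value achieved during the combined fit
tightens it — this keeps the invariant `m2_k >= m1_k` exact and `L >= 0`.

`block_fit()` scales this to large conformer pools: fit a block of
`N_B = 100` conformers (useful up to about 250), discard conformers with
`p < 0.01 * max(p)` (strict inequality), refill from the untested pool,
and repeat until the pool is exhausted. The reported populations are
those of the last block fit after pruning; subset-only optima on the
retained set are recomputed for the merit report. The refill order is
the input order by default, with a seeded shuffle available — results
depend only weakly on it.

## Ensemble analytics

With `D_ij` the Cα RMSD between conformers `i` and `j` after optimal
superposition (Kabsch, reflections forbidden), the *ensemble width* is

Γ² = Σᵢ<ⱼ pᵢpⱼ D²ᵢⱼ / Σᵢ<ⱼ pᵢpⱼ,

and the distance between two ensembles is the analogous double sum over
cross pairs. For a uniform `N`-conformer ensemble the self-distance obeys
`Γ(E,E)² = (N-1)/N · Γ(E)²` exactly. Note that the width is *not*
invariant under duplicating conformers with split populations: the
denominator runs over distinct pairs, so duplication adds zero-distance
pair weight and rescales the width by a computable factor.

`pair_correlation()` reports the population-weighted mean and standard
deviation of every residue-pair distance (two-pass moments; the one-pass
formula loses about six digits to cancellation for rigid pairs, where
the standard deviation must vanish). `flory_fit()` computes the
ensemble-averaged squared radius of gyration (or squared end-to-end
distance) of every chain segment and fits the root-mean-square values to
the Flory law `R0 (n-m)^ν` by Levenberg–Marquardt with uniform weights
over all segments of length ≥ 2 and `ν` boxed to [0.2, 0.8]. Fitting in
rms space (not log–log, not squared space) is a deliberate choice; it
shifts `ν` at about the 0.005 level relative to alternatives. The
compactness matrix `G` and proximity matrix `P` are the relative
deviations of rms segment size from the gyration-mode and end-to-end-mode
fits respectively; negative entries mark locally compact (or close)
segments, and `P` is empirically the more sensitive of the two. The
end-to-end table is fitted with its own power law rather than through the
theta-solvent identity `R² = 6 Rg²`, which holds only at `ν = 0.5`.

`sort_group()` orders conformers for presentation: average-linkage
clustering on `D_ij`, cut at the largest gap in merge heights, groups
ordered by total population. It is a generic similarity sort, not a
reimplementation of any published grouping scheme.

## The synthetic-data generators, and what they do not emulate

All tests run on synthetic systems built by the `fixtures` generators,
reproducible bit-for-bit from their seeds:

* `make_planted_system()` builds 2–3 random rigid bodies (50–150
  pseudo-atoms, Gaussian clouds of ~8 Å radius), selects reference sites
  by the production selector, and plants a ground-truth arrangement
  (optionally a translational cloud calibrated so its ensemble width
  matches a requested spread). Anchors sit on the surface atoms facing
  the partner body.
* `simulate_ddrs()` turns ground-truth distances into Gaussian DDRs with
  a noise floor (`sigma_floor`, default 3 Å, matching the label
  uncertainty convention; 1.5 Å in the planted-recovery runs, where the
  labels are exact pseudo-atoms).
* `make_random_coil_ensemble()` builds freely jointed Cα chains (3.8 Å
  bonds; `ideal`) or hard-sphere self-avoiding variants (4.5 Å exclusion;
  `self_avoiding`).
* `make_helix_coil_ensemble()` embeds rigid ideal-helix spans (1.5 Å
  rise, 100°/residue) in a *persistent* random-walk coil. The persistence
  matters: against a freely jointed chain an α-helix is more extended
  than coil for segments beyond ~13 residues, so the "helices are
  locally compact" signature only appears when the coil background is
  locally stiff, as real disordered chains are. With no spans the
  generator delegates to the random-coil generator.

These fixtures establish that the algorithms do what they claim on
systems with known answers. They do not emulate rotamer distributions of
real spin labels, experimental DEER noise and background, atomistic
scattering contrast, or sequence-specific chain statistics — so passing
tests demonstrate algorithmic correctness, not end-to-end accuracy on
any particular experimental system.

## Numerical choices and limitations

* **Finite-chain Flory bias.** For a freely jointed chain the local
  scaling exponent of segment Rg is `0.5 - 0.5/(L)` at segment length
  `L`, so the global gyration-mode fit converges to ≈0.48–0.49, not
  0.50, even on exact theory tables; sampling adds a small further
  downward (Jensen) drag. Recovery checks therefore use 150-residue
  chains with 300 conformers, where the true fitted value sits inside
  the 0.50 ± 0.03 band with margin. The end-to-end exponent is free of
  this bias.
* **Problem sizes.** The shipped checks run the planted two-body
  recovery at `T_max` up to 20,000 trials, population fitting on pools
  of 500 conformers with 15 DDRs and one SAS curve, and coil statistics
  on 100–150-residue chains with 200–400 conformers — sizes at which
  every statistical property under test is comfortably resolved.
* **Determinism.** Arrangement generation is fully deterministic for a
  fixed plan; linker growth and population fitting take explicit seeds
  and restore the caller's RNG state.
* **Degenerate inputs.** Collinear reference candidates, infeasible
  bound sets, non-embeddable matrices, zero-area distributions and
  empty restraint sets are all rejected with specific errors or counted
  diagnostics rather than propagating NaNs.
* **Floating-point limits.** Rigid-pair distance scatter reaches ~1e-9
  (two-pass moments) and compaction matrices are rigid-motion invariant
  to ~1e-8 (centered prefix sums); tighter guarantees are not attainable
  in double precision for quantities of this magnitude.
* The refinement stage treats crosslinks as one-sided (maximum-distance)
  restraints and does not re-run the full test battery after refinement
  except for clashes, which can reappear after parameter changes.

## A worked example

```{r example, eval = FALSE}
library(semiflex)

# a planted two-body system with simulated restraints
sys <- make_planted_system(n_bodies = 2, spread = 0, seed = 3)
ddrs <- simulate_ddrs(sys, sigma_floor = 1.5)
run <- run_rigi(sys$bodies, ddrs, acceptance_spec(), t_max = 600)
run$report$counts

# link the arrangements with a 20-nt RNA linker
lk <- list(linker_spec("rna", 20,
                       anchor_a = list(body = 1, anchor = "c"),
                       anchor_b = list(body = 2, anchor = "n")))
linked <- link_ensemble(run$rbas, sys$bodies, lk, seed = 1)
linked$report

# ensemble width of the linked ensemble
ensemble_width(linked$ensemble)
```

The same pipeline is exposed on the command line through the
`exec/semiflex` script (`semiflex simulate`, `semiflex rigi`,
`semiflex link`, `semiflex fit`, `semiflex analyze`).
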