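# semiflex

Integrative ensemble modeling of semistructured proteins and protein–RNA
complexes from distance-distribution restraints, and analytics for the
resulting conformational ensembles.

Many biomolecules combine well-folded domains with flexible peptide or
RNA linkers and must be described by an *ensemble* of conformers with
populations, not a single structure. Pulsed EPR (DEER/PELDOR) distance
distribution restraints (DDRs) between spin-labeled sites measure not
just mean distances but the width and shape of nanometer-range distance
distributions — exactly the information needed to estimate ensemble
width. semiflex is aimed at structural biologists integrating such
restraints with high-resolution domain structures and small-angle
scattering (SAS) data, and at anyone analyzing deposited conformational
ensembles of partially disordered proteins.

## What it computes

**Arrangement generation.** A complex of *n* rigid bodies is parametrized
by 6(*n*−1) rotation/translation parameters, but sampled through the
9*n*(*n*−1)/2 distances between three reference sites per body: each
restrained distance *rᵢ* with mean ⟨*rᵢ*⟩ and width *σᵢ* is enumerated by
*sᵢ* equidistant samples on [⟨*rᵢ*⟩−*σᵢ*, ⟨*rᵢ*⟩+*σᵢ*], subject to
triangle-bound smoothing and a cap *T* = ∏*sᵢ* ≤ *T*max. Every complete
distance matrix is embedded by metric-matrix distance geometry (both
enantiomorphs), tested against auxiliary DDRs, linker extension bounds
(3.8 Å/residue, 7 Å/nt), crosslinks, clashes and a probability score —
the geometric mean of *gᵢ* = exp(−(*r*ᵢ,sim−⟨*rᵢ*⟩)²/2*σᵢ*²) against a
threshold *p*thr — then refined until all restraint intervals are
satisfied, stopping immediately to avoid artificial ensemble narrowing.

**Flexible linkers.** Coarse-grained (Cα / P) chains grown from a 5°
fragment library with a closure bias; moderate terminal misses are fixed
by distributing stretch and rotation uniformly over the backbone.
Arrangements whose linkers cannot be built are discarded.

**Population fitting.** Conformer populations *p* are fitted on the
probability simplex against restraint subsets: DDR overlap
*o* = ∫ min(*P*pred, *P*exp) combined as *m*₁ = 1 − (∏*oᵢ*)^(1/D), and
SAS χ² with fitted scale/offset. Heterogeneous subsets are balanced by
minimizing the loss of merit *L* = (1/R) Σ (*m*₂⁽ᵏ⁾/*m*₁⁽ᵏ⁾ − 1); raw
pools are reduced block-wise (default block 100), discarding conformers
with *p* < 0.01·max(*p*).

**Ensemble analysis.** Ensemble width
Γ² = Σᵢ<ⱼ *pᵢpⱼD*ᵢⱼ²/Σᵢ<ⱼ *pᵢpⱼ* on pairwise Cα RMSDs, inter-ensemble
distances, residue pair-correlation matrices σ(*r_mn*), segment radii of
gyration with global Flory fits *R*₀(*n*−*m*)^ν, and the compactness /
proximity matrices **G** and **P** that flag locally compact segments
(e.g. preformed helices) in disordered chains.

Synthetic-data generators (planted rigid-body systems, simulated DDRs,
random-coil and helix-coil ensembles) make every stage testable without
downloads.

## A worked example

```r
library(semiflex)

# a planted two-body system with simulated Gaussian DDRs
sys  <- make_planted_system(n_bodies = 2, spread = 0, seed = 3)
ddrs <- simulate_ddrs(sys, sigma_floor = 1.5)
run  <- run_rigi(sys$bodies, ddrs, acceptance_spec(), t_max = 600)
run$report$counts
#>       screened  non_embeddable             fit   auxiliary_ddr
#>            128             212             133              45
#>      crosslink           clash     probability        accepted
#>              0               0               0              33

# link the arrangements with a 20-nt RNA linker
lk <- list(linker_spec("rna", 20,
                       anchor_a = list(body = 1, anchor = "c"),
                       anchor_b = list(body = 2, anchor = "n")))
linked <- link_ensemble(run$rbas, sys$bodies, lk, seed = 1)
linked$report$n_linked
#> [1] 33

ensemble_width(linked$ensemble)
#> [1] 1.214
```

Of 512 enumerated distance matrices (sampling resolution 3 Å), 128 fail
the triangle screen, 345 fail embedding or restraint tests, and 33
arrangements are accepted and refined; all 33 can be linked, and the
resulting ensemble has a width of 1.2 Å — tight, as expected for
restraints simulated from a single ground-truth arrangement with narrow
widths. The best accepted arrangement reproduces the planted body-2
placement to well under the sampling resolution.

The same pipeline is available from the shell via `exec/semiflex`
(subcommands `simulate`, `rigi`, `link`, `fit`, `analyze`), reading a
line-oriented restraint file (`RIGID`, `DDR`, `LINKER`, `XLINK`, `PARAM`
records) and writing multi-model PDB ensembles with plain-text reports.

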