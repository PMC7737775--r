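# Optional regression inputs

Two regression tests in `tests/testthat/test-acceptance.R` compare this
package's analytics against published analyses of deposited ensembles.
The coordinate files are distributed by their archives and are not
bundled; to enable the regressions, download them into this directory
before installing:

- `2MF1.pdb` — the 20-model solution ensemble of the RsmE/RsmZ
  (conformer R) protein–RNA complex, from the Protein Data Bank
  (https://www.rcsb.org/structure/2MF1, PDB-format download).
- `PED5AAA.pdb` — the PaaA2 antitoxin NMR/SAXS conformational ensemble
  from the Protein Ensemble Database (entry PED5AAA), as a multi-model
  PDB file.

Without these files the corresponding tests report failure with a
pointer to this note.
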