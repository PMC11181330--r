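# Example data

All files here are **synthetic**, generated by the package's own toy
generator (`makeToyModel(20, "single_domain", seed = 7)`); they mimic
the file layout of AlphaFold output, not any real protein.

- `toy_plddt.pdb` — C-alpha model with pLDDT in the B-factor column.
- `toy_pae.json` — PAE matrix, AlphaFold-DB JSON dialect.
- `toy_ensemble.pdb` — 20-frame multi-model PDB sampled from the toy's
  ground-truth elastic network.
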