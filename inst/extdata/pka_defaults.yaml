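# Default ionization constants and geometry used when building molecule
# models from sequences. All values overridable per run; pKa values for
# Glu, Lys and Cys are the nominal literature values used throughout the
# package's benchmarks, the rest (Asp, His, Arg, Tyr, termini, phosphate)
# are conventional textbook defaults.
ion_radius_nm: 0.25
groups:
  ASP: {pKa: 4.0,  valence: -1}
  GLU: {pKa: 4.3,  valence: -1}
  CYS: {pKa: 8.2,  valence: -1}
  TYR: {pKa: 10.0, valence: -1}
  LYS: {pKa: 10.4, valence:  1}
  ARG: {pKa: 12.0, valence:  1}
  HIS: {pKa: 6.0,  valence:  1}
  NTERM: {pKa: 8.0, valence:  1}
  CTERM: {pKa: 3.6, valence: -1}
  PHOSPHATE: {pKa: 2.0, valence: -1}
geometry:
  protein: {diameter_nm: 0.5, rise_nm: 0.38}
  ssDNA:   {diameter_nm: 1.0, rise_nm: 0.34, phosphates_per_unit: 1}
  dsDNA:   {diameter_nm: 2.0, rise_nm: 0.34, phosphates_per_unit: 2}
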