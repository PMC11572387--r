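Place user-supplied study data here to enable the published-value checks in
`tests/testthat/test-acceptance.R` (reinstall the package afterwards):

- `cricetinae_44x116.nex` — the 44-taxon, 116-character dental matrix
  (NEXUS, DATATYPE=STANDARD, `?` missing, `(..)` polymorphisms).
- `cricetinae_tip_ages.csv` — columns `taxon,min_ma,max_ma`, one row per
  matrix taxon; extant taxa as `0,0`.

Neither file is redistributed with the package.
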