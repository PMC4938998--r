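columns:
  sid: PUBCHEM_SID
  cid: PUBCHEM_CID
  smiles: PUBCHEM_EXT_DATASOURCE_SMILES
  outcome: PUBCHEM_ACTIVITY_OUTCOME
  potency: IC50_UM
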