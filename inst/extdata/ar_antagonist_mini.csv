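PUBCHEM_SID,PUBCHEM_CID,PUBCHEM_EXT_DATASOURCE_SMILES,PUBCHEM_ACTIVITY_OUTCOME,IC50_UM
S1,10631,CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O,Inactive,
S2,3033968,O=C1CCC2C(=C1)CCC1C2CCC2C1C=CC2,Inactive,
S3,901,OCCc1ccc2ccccc2c1,Inactive,
S4,902,CCCc1ccc2ccccc2c1,Active,17.0
S5,903,NCc1ccc2ccccc2c1,Active,2.5
S6,904,Cc1ccc2ccccc2c1,Inactive,
S6b,904,Cc1ccc2ccccc2c1,Inactive,
S7,905,OCc1ccccc1,Active,15
S7b,905,OCc1ccccc1,Inactive,
S8,906,CCOc1ccccc1.Cl,Inactive,
S9,907,CCCCCC,Inactive,
S10,908,Clc1ccccc1,,
S11,909,Brc1ccccc1,Inconclusive,
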