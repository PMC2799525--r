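peptide,exp_mw,method
DALQDDLQR,1072.48,LC-MALDI-MS/MS
STQGLSIVTHR,1197.62,LC-MALDI-MS/MS
RPLQHPPTQAEALAR,1683.91,LC-MALDI-MS/MS
QMESSEGSSETTVETPPGGR,2064.89,LC-MALDI-MS/MS
ALTDFLAAVSTQALPTLVEASPPSER,2683.33,LC-MALDI-MS/MS
EMPTSEDAQPLPR,1469.03,ESI-LC-MS/MS
STQGLSIVTHR,1197.60,ESI-LC-MS/MS
YLENTEEPIMILLNK,1819.30,ESI-LC-MS/MS
ALTDFLAAVSTQALPTLVEASPPSER,2682.91,ESI-LC-MS/MS
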