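name,fwd_seq,rev_seq,fwd_start,fwd_end,rev_start,rev_end,fwd_tail,rev_tail
PEG11_PEG11as,cttccactctccctactgcct,gcatccacaggttcccac,151950,151930,151657,151674,0,0
PEG11as,tcggggctgaggtgggaatctc,cccagctgaagggatcacagcc,154009,154030,154108,154087,0,0
rPEG11,atggatccgctttctactcccgcaacatct,aggaattcctcagtgatggtgatggtgatggaatatctggtccacgggtatc,150812,150791,150327,150348,8,30
RPLPO,caaccctgaagtgcttgacat,aggcagatggatcagcca,550,570,776,759,0,0
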