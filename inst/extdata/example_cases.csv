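case,subtype,tofts_ve,dp_f
A,wild-type,16.08,9.21
B,mutation-intact,0.08,7.00
C,mutation-codeleted,1.34,8.82
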