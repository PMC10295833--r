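sample_id,reference_mg_L,reference_sd
M1,12.8,0.2
M2,19.4,0.3
M3,9.6,0.2
M4,16.8,0.1
M5,12.6,0.3
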