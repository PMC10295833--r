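sample_id,found_mg_L,found_sd,n
M1,13.6,0.8,3
M2,17.4,0.6,3
M3,11.2,0.7,3
M4,18.1,0.7,3
M5,14.0,0.6,3
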