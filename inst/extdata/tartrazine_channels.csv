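sample_id,concentration,R,G,B,I,H,S,V,L,R_sd,G_sd,B_sd,I_sd,H_sd,S_sd,V_sd,L_sd
STD_1,1,194.5,174.7,28.9,139.1,52.3,84.3,76.0,43.3,2.4,2.1,23.4,5.4,0.6,12.3,1.0,4.0
STD_5,5,208.1,172.5,3.1,128.0,49.3,98.0,81.0,41.0,1.2,2.8,0.1,1.2,0.6,0.0,0.0,0.0
STD_10,10,206.5,151.8,1.9,120.0,43.7,99.0,80.3,40.3,1.3,0.7,0.1,0.1,0.6,0.0,0.6,0.6
STD_15,15,198.9,140.8,2.0,114.0,42.3,98.0,77.3,39.0,0.8,1.3,0.0,0.7,0.6,0.0,0.6,0.0
STD_20,20,187.0,132.7,0.9,106.9,42.0,99.0,72.7,36.3,1.0,0.6,0.1,0.2,0.0,0.0,0.6,0.6
STD_25,25,186.0,130.0,1.3,105.8,41.3,98.7,72.3,36.3,1.0,1.0,0.6,0.2,0.6,0.6,0.6,0.6
STD_30,30,181.0,125.0,1.7,102.6,41.0,98.3,70.3,36.7,1.0,1.0,0.6,0.7,0.0,0.6,0.6,0.6
M1,,203.8,148.0,1.9,116.4,42.5,97.8,78.4,40.5,1.7,1.8,0.1,1.6,1.4,1.6,2.2,1.3
M2,,192.3,136.2,1.5,111.2,41.5,97.3,74.5,37.2,2.0,1.1,0.1,1.6,1.3,2.0,1.3,1.0
M3,,192.4,137.4,1.6,111.1,40.8,94.4,75.4,37.1,1.2,1.5,0.5,0.8,0.8,1.5,1.4,1.0
M4,,193.9,136.9,1.4,110.8,42.9,97.6,75.2,36.3,1.7,1.7,0.3,0.9,1.0,1.4,1.1,1.5
M5,,205.0,150.4,1.6,117.6,43.4,97.3,80.6,40.8,1.1,1.6,0.5,1.4,0.5,1.3,1.1,1.1
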