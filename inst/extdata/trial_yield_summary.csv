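sample_set,n,min_g_per_m2,max_g_per_m2,mean_g_per_m2,sd_g_per_m2,variance,cv
training,60,520,925,686.3,107.9,11633.7,0.16
validation1,60,450,925,659.6,102.1,10417.3,0.15
validation2,60,443,788,600.6,74.0,5469.7,0.12
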