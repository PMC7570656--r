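segment_min,compound,precursor_mz,product_mz,fragmentor_v,collision_energy_v,cell_accelerator_v
2.76-4.0,Hesperidin,609.2,301.1,80,30,5
4.01-5.65,Quercetin (IS),301.1,151.1,120,25,5
5.66-6.30,Naringenin,271.1,151.1,120,20,5
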