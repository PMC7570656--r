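name,units,low,center,high
Nebulizer,psi,40,50,60
SGT,°C,300,350,400
Nozzle Voltage,V,700,1100,1500
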