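name,units,low,center,high
Gas temperature,°C,250,300,350
Gas flow,mL/min,4,7,10
Nebulizer,psi,30,45,60
Sheath gas temperature,°C,200,250,300
Sheath gas flow,mL/min,6,9,12
Capillary Voltage,V,3000,3500,4000
Nozzle Voltage,V,300,500,700
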