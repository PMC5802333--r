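name,density,rel_electron_density,ionisation_ev,hu
Air,0,0,85.7,-970
Lung,0.49,0.48,73.73,-479
Water,1,1.00,75.00,9.5
Inner bone,1.139,1.09,80.25,118
Bone mineral,1.152,1.10,80.20,127
CaCO3 30%,1.334,1.27,81.04,292
CaCO3 50%,1.562,1.47,93.23,474
Cortical bone,1.824,1.69,104.32,673
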