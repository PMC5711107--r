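# default materials registry: single (effective) elements
# columns: name,Z,A,density_g_cm3,I_eV
name,Z,A,density_g_cm3,I_eV
nickel,28,58.6934,8.908,311
tantalum,73,180.948,16.654,718
aluminum,13,26.9815,2.699,166
air,7.36,14.6,1.205e-3,85.7
water,7.42,13.3671,1.0,75
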