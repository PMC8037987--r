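force_field,rmsd,delta_core,delta_surf,delta_sim
ff99sb/TIP3P,3.8,0.16,0.18,0.17
ff99sb/TIP4P-Ew,3.5,0.16,0.20,0.18
C36m/TIP3P,3.1,0.17,0.23,0.20
C36m/TIP3Pm,3.0,0.18,0.24,0.21
AmPro13/AmW03,5.5,0.20,0.29,0.25
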