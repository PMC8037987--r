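force_field,1arb,1b6b,1bsg,1rii,2xr6,4r3f,4xq4
ff99sb/TIP3P,0.10,0.14,0.14,0.13,0.11,0.11,0.12
ff99sb/TIP4P-Ew,0.10,0.13,0.12,0.12,0.11,0.12,0.10
C36m/TIP3P,0.11,0.14,0.11,0.12,0.11,0.12,0.14
C36m/TIP3Pm,0.12,0.18,0.11,0.13,0.14,0.12,0.12
AmPro13/AmW03,0.13,0.16,0.18,0.22,0.13,0.16,0.17
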