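sex,age_min,age_max,kcal_per_m2_per_h
female,18,29,33.2
female,30,39,32.7
female,40,49,32.0
female,50,59,31.2
female,60,69,30.2
female,70,79,29.5
male,18,29,37.5
male,30,39,36.5
male,40,49,35.6
male,50,59,34.5
male,60,69,33.3
male,70,79,32.5
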