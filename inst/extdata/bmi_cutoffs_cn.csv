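sex,age_band,overweight_cutoff,obesity_cutoff
male,7,17.4,19.2
male,8,18.1,20.3
male,9,18.9,21.4
male,10,19.6,22.5
male,11,20.3,23.6
male,12,21.0,24.7
male,13,21.9,25.7
male,14,22.6,26.4
male,15,23.1,26.9
male,16,23.5,27.4
male,17,23.8,27.8
male,18,24.0,28.0
female,7,17.2,18.9
female,8,18.1,19.9
female,9,19.0,21.0
female,10,20.0,22.1
female,11,21.1,23.3
female,12,21.9,24.5
female,13,22.6,25.6
female,14,23.0,26.3
female,15,23.4,26.9
female,16,23.7,27.4
female,17,23.8,27.7
female,18,24.0,28.0
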