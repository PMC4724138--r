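sex,age,L,M,S
male,7,-1.6,15.6,0.11
male,8,-1.57,16.03,0.112
male,9,-1.54,16.49,0.114
male,10,-1.51,16.97,0.116
male,11,-1.48,17.47,0.118
male,12,-1.45,18,0.12
male,13,-1.42,18.55,0.122
male,14,-1.39,19.13,0.124
male,15,-1.36,19.73,0.126
male,16,-1.33,20.35,0.128
male,17,-1.3,21,0.13
male,18,-1.27,21.67,0.132
male,19,-1.24,22.37,0.134
female,7,-1.6,15.4,0.11
female,8,-1.57,15.81,0.112
female,9,-1.54,16.25,0.114
female,10,-1.51,16.71,0.116
female,11,-1.48,17.19,0.118
female,12,-1.45,17.7,0.12
female,13,-1.42,18.23,0.122
female,14,-1.39,18.79,0.124
female,15,-1.36,19.37,0.126
female,16,-1.33,19.97,0.128
female,17,-1.3,20.6,0.13
female,18,-1.27,21.25,0.132
female,19,-1.24,21.93,0.134
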