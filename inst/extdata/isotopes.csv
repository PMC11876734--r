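isotope,daughter_Z,endpoint_mev,branch_prob
Rb-82,36,3.378,0.818
Rb-82,36,2.601,0.129
F-18,8,0.634,0.967
Cu-64,28,0.653,0.174
Ga-68,30,1.899,0.877
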