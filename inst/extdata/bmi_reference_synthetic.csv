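sex,age_years,L,M,S,cutoff_thin2,cutoff_thin1,cutoff_overweight,cutoff_obese
female,13,-1.3,18.95,0.112,15.34,16.694,22.56,27.071
female,13.5,-1.3,19.155,0.112,15.506,16.875,22.804,27.364
female,14,-1.3,19.36,0.112,15.672,17.055,23.048,27.657
female,14.5,-1.3,19.565,0.112,15.838,17.236,23.292,27.95
female,15,-1.3,19.77,0.112,16.004,17.416,23.536,28.243
female,15.5,-1.3,19.975,0.112,16.17,17.597,23.78,28.536
female,16,-1.3,20.18,0.112,16.336,17.778,24.024,28.829
female,16.5,-1.3,20.385,0.112,16.502,17.958,24.268,29.121
female,17,-1.3,20.59,0.112,16.668,18.139,24.512,29.414
female,17.5,-1.3,20.795,0.112,16.834,18.319,24.756,29.707
female,18,-1.3,21,0.112,17,18.5,25,30
male,13,-1.9,18.25,0.115,14.297,15.559,21.025,25.23
male,13.5,-1.9,18.595,0.115,14.568,15.853,21.423,25.707
male,14,-1.9,18.94,0.115,14.838,16.147,21.82,26.184
male,14.5,-1.9,19.285,0.115,15.108,16.441,22.218,26.661
male,15,-1.9,19.63,0.115,15.378,16.735,22.615,27.138
male,15.5,-1.9,19.975,0.115,15.649,17.029,23.013,27.615
male,16,-1.9,20.32,0.115,15.919,17.324,23.41,28.092
male,16.5,-1.9,20.665,0.115,16.189,17.618,23.808,28.569
male,17,-1.9,21.01,0.115,16.459,17.912,24.205,29.046
male,17.5,-1.9,21.355,0.115,16.73,18.206,24.603,29.523
male,18,-1.9,21.7,0.115,17,18.5,25,30
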