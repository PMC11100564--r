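# Reference harvest-day summary of a 400-day anoxic incubation of Helgoland
# mud-area sediment slurries amended with a fully 13C-labelled algal lipid
# mixture (16.5 umol 13C added), at two depth zones. Measured columns:
# cumulative DIC production attributed to the added substrate (di13c_umol),
# extra indigenous-OM mineralization relative to the unamended control
# (di12c_priming_umol), indigenous mineralization in the control
# (di12c_control_umol), and 13C in new microbial biomass from labelled
# hydrolyzable amino acids (b13_umol). The b12_umol and cue columns are the
# published derived values (equal-CUE biomass estimate and carbon use
# efficiency) retained for cross-checking the report generator.
depth_zone,day,di13c_umol,di12c_priming_umol,di12c_control_umol,b13_umol,b12_umol,cue
20-45,8,0.7,1.3,0.7,0.95,2.71,0.58
20-45,46,6,3,4.0,1.85,2.16,0.24
20-45,180,6.9,0.6,16.5,1.28,3.17,0.16
20-45,400,10.4,30.6,21.0,1.08,5.36,0.09
220-245,8,0.8,8.2,2.1,0.47,6.05,0.37
220-245,46,6,29.5,12.0,1.23,8.51,0.17
220-245,180,8.2,30.8,22.0,1.17,7.53,0.12
220-245,400,11,84,16.0,1.05,9.55,0.09
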