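# Minimal example of the incubation measurement schema: one control bottle
# followed over three harvest days.
treatment,depth_zone,replicate,day,dic_umol,d13c_dic_permil
control,20-45,1,0,200,-20
control,20-45,1,100,210.5,-20.3
control,20-45,1,400,221.2,-20.5
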