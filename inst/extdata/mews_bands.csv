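component,low,high,points
systolic_bp,,71,3
systolic_bp,71,81,2
systolic_bp,81,101,1
systolic_bp,101,200,0
systolic_bp,200,,2
heart_rate,,41,2
heart_rate,41,51,1
heart_rate,51,101,0
heart_rate,101,111,1
heart_rate,111,130,2
heart_rate,130,,3
resp_rate,,9,2
resp_rate,9,15,0
resp_rate,15,21,1
resp_rate,21,30,2
resp_rate,30,,3
temperature,,35,2
temperature,35,38.5,0
temperature,38.5,,2
avpu,,1,0
avpu,1,2,1
avpu,2,3,2
avpu,3,,3
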