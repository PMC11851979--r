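condition_id,role,index,value
5,cof,1,0.29
5,cof,2,0.28
5,cof,3,0.13
5,conf,1,0.61
5,conf,2,0.7
5,conf,3,0.81
5,conf,4,0.752
5,coferr,1,1
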