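name,genus,level,form,lambda1,lambda2,lambda3,lambda4
GenusIndex,all,NA,genus_form,540,575,450,586
Alv1.1,Acropora,1,normalized_difference,395,404,NA,NA
Alv1.2,Acropora,1,normalized_difference,575,604,NA,NA
Alv1.3,Acropora,1,normalized_difference,711,732,NA,NA
Alv2.1,Acropora,2,normalized_difference,404,489,NA,NA
Alv2.2,Acropora,2,normalized_difference,595,662,NA,NA
Alv3.1,Acropora,3,normalized_difference,446,473,NA,NA
Alv3.2,Acropora,3,normalized_difference,531,555,NA,NA
Alv3.3,Acropora,3,normalized_difference,586,622,NA,NA
Alv4.1,Acropora,4,normalized_difference,446,489,NA,NA
Alv4.2,Acropora,4,normalized_difference,569,600,NA,NA
Alv4.3,Acropora,4,normalized_difference,611,671,NA,NA
Alv5.1,Acropora,5,normalized_difference,484,522,NA,NA
Alv5.2,Acropora,5,normalized_difference,695,720,NA,NA
Alv6.1,Acropora,6,normalized_difference,400,418,NA,NA
Alv6.2,Acropora,6,normalized_difference,460,484,NA,NA
Alv6.3,Acropora,6,normalized_difference,724,768,NA,NA
PLv1.1,Porites massive,1,normalized_difference,437,473,NA,NA
PLv1.2,Porites massive,1,normalized_difference,680,737,NA,NA
PLv2.1,Porites massive,2,normalized_difference,411,473,NA,NA
PLv2.2,Porites massive,2,normalized_difference,640,671,NA,NA
PLv3.1,Porites massive,3,normalized_difference,429,473,NA,NA
PLv3.2,Porites massive,3,normalized_difference,576,640,NA,NA
PLv4.1,Porites massive,4,normalized_difference,406,418,NA,NA
PLv4.2,Porites massive,4,normalized_difference,533,582,NA,NA
GLv3.1,Goniopora,3,normalized_difference,409,477,NA,NA
GLv3.2,Goniopora,3,normalized_difference,640,722,NA,NA
TLv5.1,Turbinaria,5,normalized_difference,415,442,NA,NA
TLv5.2,Turbinaria,5,normalized_difference,471,486,NA,NA
TLv5.3,Turbinaria,5,normalized_difference,500,544,NA,NA
TLv5.4,Turbinaria,5,normalized_difference,675,717,NA,NA
SLv5.1,Soft coral,5,normalized_difference,429,444,NA,NA
SLv5.2,Soft coral,5,normalized_difference,506,544,NA,NA
SLv5.3,Soft coral,5,normalized_difference,577,604,NA,NA
SLv5.4,Soft coral,5,normalized_difference,662,708,NA,NA
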