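sample,condition,role,tech_rep,ct
cont_b1,control,reference,1,19.9
cont_b1,control,target,1,21.9
cont_b1,control,reference,2,20
cont_b1,control,target,2,22
cont_b1,control,reference,3,20.1
cont_b1,control,target,3,22.1
cont_b2,control,reference,1,19.9
cont_b2,control,target,1,21.9
cont_b2,control,reference,2,20
cont_b2,control,target,2,22
cont_b2,control,reference,3,20.1
cont_b2,control,target,3,22.1
cont_b3,control,reference,1,19.9
cont_b3,control,target,1,21.9
cont_b3,control,reference,2,20
cont_b3,control,target,2,22
cont_b3,control,reference,3,20.1
cont_b3,control,target,3,22.1
trea_b1,treatment,reference,1,19.9
trea_b1,treatment,target,1,23.9
trea_b1,treatment,reference,2,20
trea_b1,treatment,target,2,24
trea_b1,treatment,reference,3,20.1
trea_b1,treatment,target,3,24.1
trea_b2,treatment,reference,1,19.9
trea_b2,treatment,target,1,23.9
trea_b2,treatment,reference,2,20
trea_b2,treatment,target,2,24
trea_b2,treatment,reference,3,20.1
trea_b2,treatment,target,3,24.1
trea_b3,treatment,reference,1,19.9
trea_b3,treatment,target,1,23.9
trea_b3,treatment,reference,2,20
trea_b3,treatment,target,2,24
trea_b3,treatment,reference,3,20.1
trea_b3,treatment,target,3,24.1
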