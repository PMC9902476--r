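covariate,metric,test,printed_p
gender,mtbr,fisher,1.000
gender,max_kih,fisher,0.023
gender,min_kil,fisher,0.805
gender,kid,fisher,0.047
age_group,mtbr,fisher,0.697
age_group,max_kih,fisher,0.546
age_group,min_kil,fisher,1.000
age_group,kid,fisher,0.684
localization,mtbr,fisher,1.000
localization,max_kih,fisher,0.016
localization,min_kil,fisher,0.825
localization,kid,fisher,<0.001
lauren,mtbr,fisher,0.042
lauren,max_kih,fisher,0.003
lauren,min_kil,fisher,0.989
lauren,kid,fisher,0.003
ypT,mtbr,tau,<0.001
ypT,max_kih,tau,0.148
ypT,min_kil,tau,0.154
ypT,kid,tau,0.432
ypN,mtbr,tau,<0.001
ypN,max_kih,tau,0.095
ypN,min_kil,tau,0.084
ypN,kid,tau,0.133
uicc,mtbr,tau,0.003
uicc,max_kih,tau,0.003
uicc,min_kil,tau,0.087
uicc,kid,tau,0.003
ypL,mtbr,fisher,<0.001
ypL,max_kih,fisher,<0.001
ypL,min_kil,fisher,0.828
ypL,kid,fisher,<0.001
ypV,mtbr,fisher,<0.003
ypV,max_kih,fisher,0.318
ypV,min_kil,fisher,1.000
ypV,kid,fisher,0.487
ypPn,mtbr,fisher,0.073
ypPn,max_kih,fisher,0.504
ypPn,min_kil,fisher,0.657
ypPn,kid,fisher,0.652
r_status,mtbr,fisher,0.359
r_status,max_kih,fisher,0.755
r_status,min_kil,fisher,1.000
r_status,kid,fisher,0.759
becker,mtbr,tau,<0.001
becker,max_kih,tau,<0.001
becker,min_kil,tau,0.012
becker,kid,tau,<0.001
mtbr_group,max_kih,fisher,0.016
mtbr_group,min_kil,fisher,0.002
mtbr_group,kid,fisher,0.015
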