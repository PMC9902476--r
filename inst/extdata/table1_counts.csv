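covariate,level,level_order,metric,n_low,n_high
gender,Male,1,mtbr,42,43
gender,Female,2,mtbr,11,10
gender,Male,1,max_kih,35,44
gender,Female,2,max_kih,15,5
gender,Male,1,min_kil,39,38
gender,Female,2,min_kil,11,9
gender,Male,1,kid,34,43
gender,Female,2,kid,14,6
age_group,<64,1,mtbr,23,26
age_group,>=64,2,mtbr,30,27
age_group,<64,1,max_kih,24,20
age_group,>=64,2,max_kih,26,29
age_group,<64,1,min_kil,22,21
age_group,>=64,2,min_kil,28,26
age_group,<64,1,kid,20,23
age_group,>=64,2,kid,28,26
localization,Proximal,1,mtbr,38,37
localization,Distal,2,mtbr,15,16
localization,Proximal,1,max_kih,29,40
localization,Distal,2,max_kih,21,9
localization,Proximal,1,min_kil,36,32
localization,Distal,2,min_kil,14,15
localization,Proximal,1,kid,26,42
localization,Distal,2,kid,22,7
lauren,Intestinal,1,mtbr,33,20
lauren,Diffuse,2,mtbr,8,15
lauren,Mixed,3,mtbr,10,11
lauren,Unclassifiable,4,mtbr,2,7
lauren,Intestinal,1,max_kih,26,21
lauren,Diffuse,2,max_kih,17,6
lauren,Mixed,3,max_kih,5,15
lauren,Unclassifiable,4,max_kih,2,7
lauren,Intestinal,1,min_kil,24,21
lauren,Diffuse,2,min_kil,11,12
lauren,Mixed,3,min_kil,10,10
lauren,Unclassifiable,4,min_kil,5,4
lauren,Intestinal,1,kid,24,21
lauren,Diffuse,2,kid,17,6
lauren,Mixed,3,kid,4,16
lauren,Unclassifiable,4,kid,3,6
ypT,ypT1,1,mtbr,12,5
ypT,ypT2,2,mtbr,12,4
ypT,ypT3,3,mtbr,28,35
ypT,ypT4,4,mtbr,1,9
ypT,ypT1,1,max_kih,8,4
ypT,ypT2,2,max_kih,10,4
ypT,ypT3,3,max_kih,26,37
ypT,ypT4,4,max_kih,6,4
ypT,ypT1,1,min_kil,5,7
ypT,ypT2,2,min_kil,5,7
ypT,ypT3,3,min_kil,33,30
ypT,ypT4,4,min_kil,7,3
ypT,ypT1,1,kid,7,5
ypT,ypT2,2,kid,9,3
ypT,ypT3,3,kid,25,38
ypT,ypT4,4,kid,7,3
ypN,ypN0,1,mtbr,22,13
ypN,ypN1,2,mtbr,16,7
ypN,ypN2,3,mtbr,12,16
ypN,ypN3,4,mtbr,3,17
ypN,ypN0,1,max_kih,20,11
ypN,ypN1,2,max_kih,9,12
ypN,ypN2,3,max_kih,13,14
ypN,ypN3,4,max_kih,8,12
ypN,ypN0,1,min_kil,15,15
ypN,ypN1,2,min_kil,5,16
ypN,ypN2,3,min_kil,17,10
ypN,ypN3,4,min_kil,13,6
ypN,ypN0,1,kid,19,11
ypN,ypN1,2,kid,7,14
ypN,ypN2,3,kid,16,11
ypN,ypN3,4,kid,6,13
uicc,I,1,mtbr,11,6
uicc,II,2,mtbr,13,3
uicc,III,3,mtbr,25,35
uicc,IV,4,mtbr,4,9
uicc,I,1,max_kih,8,4
uicc,II,2,max_kih,12,4
uicc,III,3,max_kih,27,31
uicc,IV,4,max_kih,3,10
uicc,I,1,min_kil,6,6
uicc,II,2,min_kil,3,12
uicc,III,3,min_kil,34,24
uicc,IV,4,min_kil,7,5
uicc,I,1,kid,7,5
uicc,II,2,kid,13,2
uicc,III,3,kid,25,33
uicc,IV,4,kid,3,9
ypL,ypL0,1,mtbr,46,28
ypL,ypL1,2,mtbr,7,25
ypL,ypL0,1,max_kih,44,24
ypL,ypL1,2,max_kih,6,25
ypL,ypL0,1,min_kil,35,31
ypL,ypL1,2,min_kil,15,16
ypL,ypL0,1,kid,41,25
ypL,ypL1,2,kid,7,24
ypV,ypV0,1,mtbr,53,44
ypV,ypV1,2,mtbr,0,9
ypV,ypV0,1,max_kih,47,43
ypV,ypV1,2,max_kih,3,6
ypV,ypV0,1,min_kil,45,43
ypV,ypV1,2,min_kil,5,4
ypV,ypV0,1,kid,45,43
ypV,ypV1,2,kid,3,6
ypPn,ypPn0,1,mtbr,44,35
ypPn,ypPn1,2,mtbr,9,18
ypPn,ypPn0,1,max_kih,38,34
ypPn,ypPn1,2,max_kih,12,15
ypPn,ypPn0,1,min_kil,35,35
ypPn,ypPn1,2,min_kil,15,12
ypPn,ypPn0,1,kid,36,34
ypPn,ypPn1,2,kid,12,15
r_status,pR0,1,mtbr,47,45
r_status,pR1,2,mtbr,4,8
r_status,pR0,1,max_kih,45,41
r_status,pR1,2,max_kih,5,6
r_status,pR0,1,min_kil,42,42
r_status,pR1,2,min_kil,6,5
r_status,pR0,1,kid,43,41
r_status,pR1,2,kid,5,6
becker,1b,1,mtbr,27,2
becker,2,2,mtbr,14,5
becker,3,3,mtbr,12,46
becker,1b,1,max_kih,16,6
becker,2,2,max_kih,14,5
becker,3,3,max_kih,20,38
becker,1b,1,min_kil,5,15
becker,2,2,min_kil,10,9
becker,3,3,min_kil,35,23
becker,1b,1,kid,16,4
becker,2,2,kid,15,4
becker,3,3,kid,17,41
mtbr_group,responder,1,max_kih,27,19
mtbr_group,non-responder,2,max_kih,23,30
mtbr_group,responder,1,min_kil,15,29
mtbr_group,non-responder,2,min_kil,35,18
mtbr_group,responder,1,kid,28,16
mtbr_group,non-responder,2,kid,20,33
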