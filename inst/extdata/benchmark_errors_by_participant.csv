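clip_type,participant,TF,DF,rate_pct,H_L,H_R,H_LR,V_L,V_R,V_LR,C_L,C_R,C_LR
DSM,1,4465,3893,87.2,7.9,8.0,7.7,4.5,4.5,4.5,9.1,9.2,8.9
DSM,2,4464,4335,97.1,7.6,6.5,6.8,3.7,3.8,3.7,8.4,7.6,7.7
DSM,3,4433,4322,97.5,5.9,6.9,5.9,5.7,5.5,5.3,8.2,8.8,7.9
DSM,4,4464,4402,98.6,7.7,7.2,5.7,5.0,4.8,4.5,9.2,8.7,7.3
DSM,5,4465,4465,100,5.9,5.2,4.5,4.5,4.1,4.0,7.4,6.7,6.0
DSM,6,4464,4464,100,5.3,5.5,5.1,4.6,4.6,4.5,7.0,7.2,6.8
DSM,8,4465,4020,90.0,9.2,10.1,8.7,4.8,4.5,4.4,10.4,11.0,9.8
DSM,9,4464,4362,97.7,10.1,6.8,7.5,3.7,3.7,3.6,10.8,7.8,8.3
DSM,10,4464,4450,99.7,9.1,9.5,9.2,4.5,4.8,4.6,10.2,10.7,10.3
DSM,11,4465,4465,100,4.7,3.7,3.5,4.5,6.4,3.5,6.5,7.4,4.9
DSM,14,4465,4464,100,4.7,4.3,3.6,3.7,3.6,3.3,6.0,5.5,4.9
DSM,15,4465,4465,100,3.8,3.4,3.2,4.1,4.2,4.2,5.6,5.4,5.3
DSM,16,4465,4286,96.0,6.1,6.6,4.9,4.0,4.1,3.9,7.3,7.8,6.2
DSM,Avg,4462,4338,97.2,6.8,6.5,5.9,4.4,4.5,4.2,8.1,7.9,7.2
CSM,1,4457,3370,75.6,9.7,11.2,10.3,4.0,4.1,4.0,10.5,12.0,11.0
CSM,2,4457,4360,97.8,7.9,7.6,7.6,3.2,3.2,3.1,8.5,8.2,8.2
CSM,3,4458,3962,88.9,6.0,7.0,5.9,4.1,3.8,4.0,7.3,8.0,7.1
CSM,4,4494,4333,96.4,8.1,7.0,6.7,3.7,3.8,3.7,8.9,8.0,7.7
CSM,5,4458,4394,98.6,5.3,6.1,5.1,3.8,3.6,3.7,6.5,7.1,6.3
CSM,6,4458,4458,100,7.7,8.4,7.6,4.4,4.5,4.1,8.8,9.6,8.6
CSM,8,4458,3510,78.7,10.6,9.3,9.6,4.1,4.5,4.3,11.4,10.3,10.5
CSM,9,4457,4199,94.2,7.4,7.2,7.2,4.0,3.8,3.8,8.4,8.1,8.1
CSM,10,4492,4492,100,6.5,7.3,6.6,5.0,4.9,4.9,8.2,8.8,8.3
CSM,11,4458,4360,97.8,6.0,6.5,6.2,3.6,3.6,3.6,7.0,7.4,7.1
CSM,14,4458,4439,99.6,4.1,3.3,3.4,3.1,4.1,3.4,5.2,5.2,4.9
CSM,15,4458,4458,100,3.6,3.5,2.9,3.2,3.2,3.1,4.8,4.8,4.2
CSM,16,4458,4293,96.3,5.5,9.7,5.5,4.2,5.8,3.8,6.9,11.3,6.6
CSM,Avg,4463,4202,94.2,6.8,7.2,6.5,3.9,4.1,3.8,7.9,8.4,7.6
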