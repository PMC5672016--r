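treatment,bap,kin,tdz,iba,naa,pr_mean,pr_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se
1 mg/l BAP + 0.1 mg/l IBA,1,0,0,0.1,0,10.8,0.37,2.9,0.03,0.17,0.008,3.65,0.06
1 mg/l BAP + 0.1 mg/l NAA,1,0,0,0,0.1,8.6,0.24,2.3,0.03,0.24,0.021,3.85,0.06
1.5 mg/l KIN + 0.05 mg/l IBA,0,1.5,0,0.05,0,7,0.32,1.9,0.01,0.41,0.01,4.2,0.05
1.5 mg/l KIN + 0.05 mg/l NAA,0,1.5,0,0,0.05,9.6,0.24,2.05,0.03,0.32,0.008,3.95,0.05
1.5 mg/l KIN + 0.1 mg/l IBA,0,1.5,0,0.1,0,5,0.32,1.6,0.02,0.42,0.011,2.5,0.08
1.2 mg/l BAP + 0.098 mg/l IBA,1.2,0,0,0.098,0,10.2,0.37,2.82,0.02,0.19,0.005,3.85,0.1
0.98 mg/l BAP + 0.1 mg/l NAA,0.98,0,0,0,0.1,7.6,0.24,2.5,0.04,0.24,0.006,4,0.08
1.46 mg/l KIN + 0.01 mg/l IBA,0,1.46,0,0.01,0,6.8,0.2,2.36,0.02,0.38,0.007,4.35,0.06
1.53 mg/l KIN + 0.048 mg/l NAA,0,1.53,0,0,0.048,9.4,0.24,2.4,0.04,0.33,0.009,4.1,0.06
1.5 mg/l KIN + 0.052 mg/l IBA,0,1.5,0,0.052,0,4.4,0.24,1.84,0.04,0.46,0.008,2.35,0.06
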