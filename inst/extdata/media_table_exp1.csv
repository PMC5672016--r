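experiment_id,media_id,bap,kin,tdz,iba,naa,ns_mean,ns_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se,n_replicates
1,1,0,0,0,0,0,1.33,0.21,2.53,0.06,0.01,0.01,4.83,0.11,6
1,2,0,0,0,0.05,0,1.33,0.21,2.12,0.05,0.02,0.008,4.83,0.11,6
1,3,0,0,0,0.1,0,1.67,0.16,2.18,0.06,0.07,0.02,4.92,0.08,6
1,4,0,0,0,0.15,0,1.67,0.16,1.98,0.03,0.04,0.01,5,0,6
1,5,0.5,0,0,0,0,3.17,0.66,1.87,0.03,0.09,0.05,4.58,0.15,6
1,6,0.5,0,0,0.05,0,3.67,0.71,2.32,0.03,0.1,0.01,4.33,0.11,6
1,7,0.5,0,0,0.1,0,3.33,0.56,1.86,0.04,0.14,0.03,4.17,0.11,6
1,8,0.5,0,0,0.15,0,3.17,0.48,2.38,0.05,0.19,0.02,4.17,0.11,6
1,9,1,0,0,0,0,8.33,0.21,2.82,0.03,0.16,0.02,3.83,0.11,6
1,10,1,0,0,0.05,0,9,0.26,3.03,0.04,0.18,0.01,3.66,0.11,6
1,11,1,0,0,0.1,0,10.67,0.21,2.63,0.02,0.22,0.03,3.41,0.15,6
1,12,1,0,0,0.15,0,6.67,0.33,2.18,0.07,0.27,0.04,3.25,0.11,6
1,13,1.5,0,0,0,0,3.67,0.42,1.92,0.03,0.18,0.04,3.08,0.15,6
1,14,1.5,0,0,0.05,0,3.33,0.33,2.12,0.05,0.21,0.05,2.83,0.11,6
1,15,1.5,0,0,0.1,0,3.83,0.7,2.45,0.03,0.18,0.03,2.75,0.21,6
1,16,1.5,0,0,0.15,0,2.67,0.33,2.04,0.04,0.27,0.04,2.58,0.15,6
1,17,2,0,0,0,0,3,0.77,1.9,0.03,0.36,0.09,2.17,0.17,6
1,18,2,0,0,0.05,0,2.33,0.33,1.75,0.03,0.2,0.02,1.83,0.11,6
1,19,2,0,0,0.1,0,2.33,0.49,2.68,0.04,0.31,0.04,1.42,0.15,6
1,20,2,0,0,0.15,0,4,1.13,1.75,0.04,0.35,0.04,1.08,0.08,6
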