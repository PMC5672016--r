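experiment_id,media_id,bap,kin,tdz,iba,naa,ns_mean,ns_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se,n_replicates
2,1,0,0,0,0,0,1.16,0.16,2.67,0.04,0,0,4.83,0.11,6
2,2,0,0,0,0,0.05,1.83,0.16,2.13,0.05,0.01,0.009,4.83,0.11,6
2,3,0,0,0,0,0.1,1.17,0.17,2.13,0.06,0.02,0.01,4.91,0.08,6
2,4,0,0,0,0,0.15,1.17,0.17,1.95,0.02,0.06,0.009,5,0,6
2,5,0.5,0,0,0,0,2.83,0.4,1.96,0.04,0.07,0.014,4.58,0.15,6
2,6,0.5,0,0,0,0.05,4.17,0.4,2.12,0.05,0.09,0.02,4.42,0.08,6
2,7,0.5,0,0,0,0.1,4,0.58,2.08,0.11,0.11,0.03,4.42,0.11,6
2,8,0.5,0,0,0,0.15,3.33,0.42,1.99,0.08,0.16,0.02,4.08,0.15,6
2,9,1,0,0,0,0,6.67,0.33,2.02,0.03,0.15,0.01,4,0,6
2,10,1,0,0,0,0.05,7.5,0.22,1.94,0.05,0.19,0.01,3.92,0.08,6
2,11,1,0,0,0,0.1,8.5,0.22,1.91,0.04,0.23,0.009,3.58,0.15,6
2,12,1,0,0,0,0.15,6,0.37,1.77,0.04,0.26,0.01,3.5,0,6
2,13,1.5,0,0,0,0,3.83,0.4,1.8,0.03,0.21,0.01,3.42,0.08,6
2,14,1.5,0,0,0,0.05,3.67,0.33,1.8,0.04,0.25,0.01,3.12,0.11,6
2,15,1.5,0,0,0,0.1,3.33,0.5,1.81,0.05,0.28,0.01,3,0.13,6
2,16,1.5,0,0,0,0.15,2.83,0.31,1.74,0.04,0.32,0.006,2.75,0.11,6
2,17,2,0,0,0,0,2.5,0.43,1.74,0.03,0.24,0.007,2.5,0.13,6
2,18,2,0,0,0,0.05,2.33,0.33,1.64,0.02,0.27,0.006,2.33,0.11,6
2,19,2,0,0,0,0.1,2,0.37,1.6,0.03,0.33,0.01,2.17,0.11,6
2,20,2,0,0,0,0.15,2.67,0.33,1.55,0.02,0.35,0.01,1.92,0.08,6
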