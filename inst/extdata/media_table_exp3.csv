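experiment_id,media_id,bap,kin,tdz,iba,naa,ns_mean,ns_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se,n_replicates
3,1,0,0,0,0.05,0,1,0,2.16,0.09,0.02,0.005,4.6,0.19,5
3,2,0,0,0,0.1,0,1,0,2.04,0.06,0.03,0.003,4,0.22,5
3,3,0,0,0,0.15,0,1,0,1.98,0.12,0.02,0.003,4.1,0.19,5
3,4,0,0.5,0,0.05,0,2.2,0.2,1.76,0.07,0.12,0.017,3.6,0.19,5
3,5,0,0.5,0,0.1,0,3,0.32,1.62,0.06,0.18,0.019,3.4,0.19,5
3,6,0,0.5,0,0.15,0,3.6,0.24,1.5,0.05,0.31,0.012,3.1,0.19,5
3,7,0,1,0,0.05,0,5.6,0.4,1.42,0.04,0.35,0.014,2.9,0.19,5
3,8,0,1,0,0.1,0,5,0.32,1.28,0.04,0.39,0.014,2.7,0.12,5
3,9,0,1,0,0.15,0,5.6,0.51,1.26,0.05,0.44,0.005,2.3,0.2,5
3,10,0,1.5,0,0.05,0,7,0.32,1.34,0.05,0.45,0.015,2,0.22,5
3,11,0,1.5,0,0.1,0,4.8,0.37,1.22,0.04,0.47,0.015,1.9,0.19,5
3,12,0,1.5,0,0.15,0,3.4,0.24,1.08,0.05,0.5,0.1,1.4,0.19,5
3,13,0,2,0,0.05,0,3,0.32,1.18,0.06,0.5,0.021,2.3,0.7,5
3,14,0,2,0,0.1,0,2.4,0.24,1.08,0.04,0.51,0.027,2,0.76,5
3,15,0,2,0,0.15,0,1.8,0.2,1.08,0.04,0.63,0.017,1.5,0.63,5
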