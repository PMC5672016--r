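experiment_id,media_id,bap,kin,tdz,iba,naa,ns_mean,ns_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se,n_replicates
4,1,0,0,0,0,0.05,1,0,2.06,0.13,0.02,0.02,5,0,5
4,2,0,0,0,0,0.1,1,0,2.14,0.17,0.07,0.12,4.7,0.27,5
4,3,0,0,0,0,0.15,1,0,2.46,0.11,0.02,0.01,4.6,0.22,5
4,4,0,0.5,0,0,0.05,3,0.71,1.9,0.07,0.07,0.03,4.3,0.27,5
4,5,0,0.5,0,0,0.1,3.6,1.14,2.28,0.08,0.12,0.05,4,0,5
4,6,0,0.5,0,0,0.15,4.6,1.14,2.38,0.24,0.17,0.06,4,0,5
4,7,0,1,0,0,0.05,5.4,0.89,1.92,0.08,0.16,0.02,3.6,0.22,5
4,8,0,1,0,0,0.1,6.8,0.84,1.74,0.11,0.22,0.03,3.5,0,5
4,9,0,1,0,0,0.15,7.4,0.89,1.66,0.05,0.27,0.03,3.2,0.27,5
4,10,0,1.5,0,0,0.05,6.4,0.55,1.76,0.11,0.25,0.03,3,0,5
4,11,0,1.5,0,0,0.1,9.8,0.84,1.52,0.16,0.3,0.04,2.7,0.27,5
4,12,0,1.5,0,0,0.15,6.2,0.84,1.64,0.13,0.33,0.03,2.5,0,5
4,13,0,2,0,0,0.05,3.8,0.45,1.52,0.08,0.3,0.05,2.2,0.27,5
4,14,0,2,0,0,0.1,4.8,1.09,1.28,0.08,0.36,0.03,2,0,5
4,15,0,2,0,0,0.15,2.8,0.45,1.32,0.08,0.39,0.02,1.3,0.27,5
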