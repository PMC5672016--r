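experiment_id,media_id,bap,kin,tdz,iba,naa,ns_mean,ns_se,ls_mean,ls_se,cw_mean,cw_se,qi_mean,qi_se,n_replicates
5,1,0,0,0,0.05,0,1,0,1.96,0.02,0.04,0.007,3.5,0,5
5,2,0,0,0,0.1,0,1,0,1.82,0.04,0.05,0.003,3.3,0.12,5
5,3,0,0,0,0.15,0,1,0,1.66,0.02,0.04,0.004,3.1,0.1,5
5,4,0,0,0.5,0.05,0,1.4,0.24,1.76,0.02,0.21,0.012,2.9,0.1,5
5,5,0,0,0.5,0.1,0,2,0,1.6,0.03,0.39,0.013,2.6,0.1,5
5,6,0,0,0.5,0.15,0,3,0,1.52,0.02,0.48,0.029,2.5,0,5
5,7,0,0,1,0.05,0,2.6,0.4,1.62,0.04,0.38,0.012,2.3,0.12,5
5,8,0,0,1,0.1,0,3.8,0.73,1.42,0.04,0.44,0.007,2,0,5
5,9,0,0,1,0.15,0,2.8,0.37,1.3,0.03,0.56,0.023,1.9,0.1,5
5,10,0,0,1.5,0.05,0,2.8,0.37,1.42,0.04,0.41,0.017,1.6,0.1,5
5,11,0,0,1.5,0.1,0,5,0,1.3,0.03,0.47,0.016,1.5,0,5
5,12,0,0,1.5,0.15,0,4.4,0.24,1.18,0.02,0.53,0.026,1.1,0.1,5
5,13,0,0,2,0.05,0,4.2,0.58,1.32,0.04,0.41,0.013,1,0,5
5,14,0,0,2,0.1,0,3.6,0.24,1.1,0.03,0.55,0.02,0.8,0.12,5
5,15,0,0,2,0.15,0,2.2,0.49,0.84,0.05,0.7,0.022,0.5,0,5
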