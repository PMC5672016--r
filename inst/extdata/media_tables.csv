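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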