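subject,group,lambda_med,lambda_pre,width_med,width_pre,shuffled_width_med,shuffled_width_pre
C1,chi,5.49,3.22,0.66,0.24,0.13,0.19
C2,chi,3.83,2.95,0.43,0.21,0.08,0.09
C3,chi,3.9,2.94,0.59,0.3,0.21,0.05
C4,chi,3.96,2.61,0.45,0.39,0.05,0.02
C5,chi,3.49,3.01,0.41,0.31,0.26,0.17
C6,chi,3.89,3.12,0.28,0.28,0.14,0.14
C7,chi,3.07,2.33,0.53,0.32,0.16,0.22
C8,chi,3.89,3.45,0.68,0.43,0.09,0.11
Y1,kundalini,5.19,1.42,NA,NA,NA,NA
Y2,kundalini,3.25,1.9,NA,NA,NA,NA
Y3,kundalini,3.6,2.28,NA,NA,NA,NA
Y4,kundalini,1.94,1.32,NA,NA,NA,NA
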