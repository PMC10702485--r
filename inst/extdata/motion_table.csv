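patient,gating,sim_ap,mean_ap,min_ap,max_ap,sim_cc,mean_cc,min_cc,max_cc
1,FB,0.06,0.09,0.06,0.11,0.11,0.09,0.07,0.12
2,FB,0.15,0.10,0.08,0.15,0.10,0.10,0.07,0.14
3,FB,0.13,0.12,0.07,0.17,0.06,0.06,0.04,0.08
4,FB,0.06,0.07,0.06,0.08,0.08,0.06,0.06,0.08
5,FB,0.10,0.09,0.05,0.12,0.17,0.12,0.05,0.17
6,FB,0.10,0.08,0.04,0.11,0.11,0.08,0.05,0.11
7,DIBH,0.07,0.08,0.04,0.13,0.04,0.11,0.04,0.20
8,DIBH,0.07,0.09,0.06,0.12,0.07,0.08,0.04,0.12
9,DIBH,0.09,0.08,0.04,0.12,0.13,0.09,0.06,0.13
10,DIBH,0.06,0.09,0.04,0.11,0.05,0.11,0.05,0.22
11,DIBH,0.08,0.11,0.08,0.17,0.06,0.14,0.06,0.21
12,DIBH,0.15,0.13,0.07,0.18,0.12,0.12,0.09,0.17
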