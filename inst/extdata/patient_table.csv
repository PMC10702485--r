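patient,gtv_motion_cc,v_lung_cc,v_gtv_cc,ratio_gtv_lung_1e4,hepatic_dome_motion_cm
1,0.09,1934.39,1.92,9.93,1.68
2,0.10,1447.68,0.47,3.25,1.36
3,0.06,2301.69,1.86,8.08,1.28
4,0.06,2395.99,8.95,37.35,2.00
5,0.12,2764.78,0.42,1.52,1.60
6,0.08,2132.50,36.49,171.11,2.60
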