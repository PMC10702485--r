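structure,index,unit,p1,p2,p3,p4,p5,p6
PTV,V80%,%,1.00,0.00,5.70,5.54,0.09,3.98
PTV,V100%,%,5.01,9.11,12.97,15.58,6.88,3.37
GTV,V80%,%,0.00,0.00,0.00,0.03,0.00,-0.16
GTV,V100%,%,-14.17,-13.61,4.98,20.58,-6.20,-2.84
GTV,V100%,cc,-0.27,-0.07,-0.26,-1.27,-0.06,-5.17
homolateral_lung,V20Gy,%,-1.83,-1.67,-0.83,-1.66,-0.64,-0.22
homolateral_lung,Dmean,Gy,-0.91,-0.78,-0.35,-0.71,-0.57,-0.01
homolateral_lung,V5Gy,%,-3.80,-3.34,-1.74,-2.25,-2.74,-0.32
contralateral_lung,Dmax,Gy,-0.65,-1.27,-0.36,-2.92,-4.14,-1.02
contralateral_lung,Dmean,Gy,-0.18,-0.01,-0.13,-0.14,-0.34,-0.29
contralateral_lung,V5Gy,%,-0.03,-0.85,-0.19,-1.37,-1.52,-2.44
chest_wall,Dmax,Gy,-5.10,-3.73,-0.70,-1.82,-3.39,-0.56
trachea_bronchial_tree,Dmax,Gy,-6.85,-2.57,-1.85,-0.03,-5.82,-0.88
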