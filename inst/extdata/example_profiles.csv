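sample_id,level,category,dye01_dR,dye02_dR,dye03_dR,dye04_dR,dye05_dR,dye06_dR,dye07_dR,dye08_dR,dye09_dR,dye10_dR,dye11_dR,dye12_dR,dye01_dG,dye02_dG,dye03_dG,dye04_dG,dye05_dG,dye06_dG,dye07_dG,dye08_dG,dye09_dG,dye10_dG,dye11_dG,dye12_dG,dye01_dB,dye02_dB,dye03_dB,dye04_dB,dye05_dB,dye06_dB,dye07_dB,dye08_dB,dye09_dB,dye10_dB,dye11_dB,dye12_dB
EX1,0.2,mixture,7.2,4.8,0.49,0.25,0.21,0.54,1.2,0.7,0.31,4.2,0.15,0.22,7.3,0.49,0.3,0.2,0.53,0.34,1.9,0.53,0.04,1.3,0.47,5.4,0.18,0.56,0.44,0.34,0.41,0.6,1.3,0.05,0.64,0.36,0.51,0.25
EX2,0.4,mixture,12,5.1,0.55,1.1,0.5,0.053,2,0.79,0.65,8.4,0.62,0.31,11,0.024,0.53,2.2,1.3,0.52,1.5,0.22,0.2,2.6,0.18,8.6,1.7,0.11,1.1,2.6,0.89,1.8,6.3,1,3,0.022,1.1,4.4
EX3,0.6,mixture,7.9,2,3.4,5.4,1.7,4.8,1.7,2.4,0.37,8.2,0.35,1.8,9.3,7.4,3,5.4,4.2,4.7,0.86,3.1,5.8,0.74,0.25,10,3.7,7.6,5.8,0.98,4.9,12,4.7,4,5.5,0.024,1,4.2
EX4,0.8,mixture,8.1,6.8,0.031,0.089,0.4,1.7,1.4,0.87,0.068,9.3,1.4,1.8,6.7,6.1,0.33,0.4,0.66,0.19,1.2,1.2,0.09,1.5,1.6,111,2.3,6.8,1.1,0.86,1.1,1.4,5.1,0.049,1.8,0.3,1.8,0.31
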