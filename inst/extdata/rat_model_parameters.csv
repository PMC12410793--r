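rat,p0,p1,p2,p3,p4,p5
DR1,2.48,0.01,368.12,9.5,4.95,20.45
DR2,0.98,0.01,425.84,9.5,2.47,20.45
DR3,11.14,0.02,1439.53,9.5,6.23,20.45
DR4,7.11,0.02,543.48,9.5,3.61,20.45
DR5,9.21,0.03,802.50,9.5,4.29,20.45
DR6,7.84,0.02,732.32,9.5,8.87,20.45
DR7,1.73,0.00,1080.85,9.5,6.75,20.45
DR8,2.05,0.01,318.11,9.5,6.09,20.45
DR9,6.39,0.02,390.04,9.5,10.49,20.45
DR10,8.64,0.02,810.89,9.5,6.06,20.45
DR11,0.85,0.00,473.25,9.5,5.12,20.45
DR12,6.94,0.01,247.05,9.5,7.73,20.45
DR13,13.50,0.04,328.73,9.5,9.25,20.45
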