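name,chromosome,map_position_cM,mean_he,sd_he,ceph_he
D3S1297,3,8.3,0.720,0.055,0.820
D3S1304,3,22.3,0.798,0.025,0.800
D3S1263,3,36.1,0.883,0.021,0.860
D3S1266,3,52.6,0.702,0.040,0.730
D3S1285,3,91.2,0.709,0.048,0.730
D3S1278,3,129.7,0.759,0.062,0.870
D3S1292,3,146.6,0.871,0.022,0.850
D3S1279,3,169.6,0.767,0.053,0.850
D3S1614,3,177.8,0.750,0.041,0.830
D3S1580,3,207.7,0.825,0.046,0.840
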