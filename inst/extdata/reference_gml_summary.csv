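group,gefc,getc,gpec,gsec,gml,gefc_adj,getc_adj,gpec_adj,gsec_adj,gml_adj
Heilongjiang,1.014,1.013,1.000,1.015,1.025,0.997,1.041,0.996,1.004,1.037
Liaoning,1.032,1.000,1.000,1.033,1.023,1.021,1.022,1.000,1.021,1.038
Jilin,1.020,0.993,1.020,1.000,1.010,1.028,1.011,1.005,1.022,1.039
Neimenggu,1.012,1.024,1.005,1.010,1.023,1.045,1.037,1.002,1.044,1.047
Hebei,1.019,1.001,1.021,0.999,1.017,1.009,1.019,1.016,0.994,1.024
Shandong,1.015,0.999,1.011,1.027,1.009,1.027,1.018,1.008,1.025,1.017
Anhui,1.016,0.998,1.018,1.000,1.008,1.006,1.023,1.007,0.997,1.024
Henan,1.016,0.998,1.001,1.014,1.007,1.025,1.014,1.010,1.028,1.022
Jiangsu,1.025,1.022,1.022,1.004,1.001,0.999,1.026,1.011,0.991,1.009
Sichuan,1.016,1.006,1.008,1.008,0.994,1.007,1.044,1.007,0.998,1.011
Hubei,0.993,0.996,0.992,1.004,0.982,0.990,1.023,0.992,1.001,1.006
Hunan,1.008,0.994,1.010,1.001,0.989,0.995,1.025,1.008,0.987,1.005
Jiangxi,1.002,1.006,0.991,1.012,1.000,1.003,1.024,0.997,1.004,1.015
Northeast,1.020,1.007,1.006,1.014,1.020,1.023,1.028,1.001,1.022,1.040
Huang-Huai-Hai,1.018,1.004,1.015,1.009,1.008,1.013,1.020,1.011,1.007,1.019
Yangtze,1.004,1.000,1.000,1.007,0.991,0.999,1.029,1.001,0.998,1.009
Average,1.014,1.004,1.008,1.010,1.007,1.012,1.025,1.005,1.009,1.023
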