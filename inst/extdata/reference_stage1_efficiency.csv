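region,cte,pte,se
Heilongjiang,0.866,0.894,0.966
Liaoning,0.798,0.913,0.877
Jilin,0.917,0.921,0.995
Neimenggu,0.813,0.871,0.937
Hebei,0.581,0.586,0.991
Shandong,0.594,0.621,0.959
Anhui,0.556,0.569,0.978
Henan,0.576,0.669,0.875
Jiangsu,0.677,0.694,0.977
Sichuan,0.841,0.857,0.983
Hubei,0.767,0.789,0.974
Hunan,0.849,0.853,0.994
Jiangxi,0.871,0.892,0.976
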