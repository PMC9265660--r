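region,cte,pte,se
Heilongjiang,0.807,0.965,0.833
Liaoning,0.557,0.946,0.590
Jilin,0.753,0.952,0.787
Neimenggu,0.541,0.901,0.606
Hebei,0.553,0.682,0.806
Shandong,0.618,0.681,0.904
Anhui,0.525,0.665,0.788
Henan,0.622,0.692,0.902
Jiangsu,0.615,0.765,0.804
Sichuan,0.663,0.899,0.737
Hubei,0.569,0.825,0.692
Hunan,0.686,0.907,0.757
Jiangxi,0.596,0.952,0.627
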