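year,cte_stage1,cte_stage3,pte_stage1,pte_stage3,se_stage1,se_stage3
2000,0.727,0.528,0.782,0.828,0.938,0.660
2001,0.715,0.533,0.756,0.826,0.950,0.666
2002,0.772,0.551,0.790,0.837,0.977,0.679
2003,0.688,0.508,0.734,0.794,0.946,0.657
2004,0.719,0.568,0.755,0.817,0.957,0.708
2005,0.705,0.574,0.734,0.805,0.963,0.725
2006,0.712,0.601,0.740,0.807,0.963,0.755
2007,0.688,0.587,0.717,0.780,0.960,0.763
2008,0.726,0.635,0.754,0.818,0.963,0.785
2009,0.683,0.607,0.712,0.774,0.959,0.791
2010,0.703,0.654,0.728,0.794,0.965,0.824
2011,0.734,0.684,0.762,0.810,0.962,0.845
2012,0.739,0.689,0.763,0.813,0.966,0.851
2013,0.759,0.709,0.784,0.825,0.966,0.862
2014,0.745,0.708,0.767,0.818,0.968,0.867
2015,0.760,0.737,0.795,0.842,0.954,0.875
2016,0.773,0.743,0.812,0.846,0.950,0.881
2017,0.784,0.761,0.837,0.870,0.936,0.875
2018,0.791,0.756,0.855,0.907,0.931,0.839
2019,0.798,0.761,0.871,0.911,0.927,0.836
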