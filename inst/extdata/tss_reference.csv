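percentile,threshold,TSS,sensitivity,specificity,maxTSS
0.1,0.00013,0.094512,0.994417,0.100095,1.094512
0.2,0.00027,0.184416,0.985105,0.199312,1.184416
0.25,0.00034,0.215538,0.979644,0.235894,1.215538
0.3,0.00047,0.266873,0.969356,0.297516,1.266873
0.4,0.00076,0.343016,0.944393,0.398623,1.343016
0.5,0.0011,0.406785,0.914749,0.492036,1.406785
0.6,0.0018,0.460293,0.857094,0.603199,1.460293
0.7,0.0027,0.482525,0.786251,0.696274,1.482525
0.75,0.00342,0.478716,0.728986,0.74973,1.478716
0.8,0.004,0.471159,0.687006,0.784152,1.471159
0.9,0.008,0.408702,0.514871,0.893831,1.408702
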