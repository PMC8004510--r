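Nz 0.0000 94.0000 0.0000
LPA -94.0000 0.0000 0.0000
RPA 94.0000 0.0000 0.0000
E01 19.2051 0.0000 92.0172
E02 -24.2652 22.2289 88.0516
E03 3.6735 -41.8576 84.0859
E04 29.9110 39.0137 80.1203
E05 -54.2618 -9.5981 76.1547
E06 50.7990 -32.3141 72.1891
E07 -16.7873 62.4480 68.2234
E08 -31.6215 -60.8853 64.2578
E09 67.7410 24.7389 60.2922
E10 -69.5616 28.7140 56.3266
E11 33.0880 -70.7072 52.3609
E12 24.1177 76.8910 48.3953
E13 -71.6717 -41.5352 44.4297
E14 82.8660 -18.2179 40.4641
E15 -49.8205 70.8645 36.4984
E16 -11.3335 -87.4595 32.5328
E17 68.4774 57.7128 28.5672
E18 -90.6461 3.7485 24.6016
E19 65.0046 -64.6882 20.6359
E20 -4.2732 92.4113 16.6703
E21 -59.6740 -71.5094 12.7047
E22 92.7570 12.4803 8.7391
E23 -77.0611 53.6171 4.7734
E24 20.6305 -91.7046 0.8078
E25 46.7086 81.5128 -3.1578
E26 -89.2956 -28.4877 -7.1234
E27 84.7365 -39.1504 -11.0891
E28 -35.8213 85.5932 -15.0547
E29 -31.1564 -86.6228 -19.0203
E30 80.6817 42.4041 -22.9859
E31 -87.0789 22.9537 -26.9516
E32 48.0102 -74.6669 -30.9172
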