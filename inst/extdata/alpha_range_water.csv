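energy_MeV,csda_range_um
0.02,0.066678732
0.023034046,0.074589277
0.026528363,0.083508993
0.030552776,0.093584765
0.035187702,0.10498919
0.040525757,0.11792596
0.046673606,0.13263662
0.053754099,0.14940881
0.061908719,0.16858672
0.071300412,0.19058399
0.082116848,0.21589994
0.094574161,0.2451399
0.10892128,0.27904074
0.12544488,0.31850296
0.14447516,0.36463114
0.16639237,0.4187849
0.19163447,0.48264333
0.22070586,0.55828626
0.25418744,0.64829715
0.29274826,0.75589326
0.33715883,0.88509048
0.3883066,1.0409123
0.4472136,1.2296544
0.51505692,1.4592211
0.59319223,1.739551
0.68318084,2.0831583
0.78682094,2.5058198
0.90618347,3.0274473
1.0436536,3.6731961
1.2019782,4.474873
1.384321,5.4727265
1.5943257,6.7177216
1.8361885,8.2744313
2.1147425,10.224714
2.4355538,12.672389
2.8050329,15.749178
3.2305627,19.622273
3.7206465,24.503945
4.2850771,30.663776
4.935133,38.44422
5.683804,48.280389
6.54605,60.725225
7.5391007,76.481531
8.6827995,96.442704
10,121.74458
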