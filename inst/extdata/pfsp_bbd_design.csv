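run_id,time_min,temperature_C,solvent_mL,ta_mg_per_100g,ta_sd,tpc_mg_gae_per_100g,tpc_sd
1,5,30,50,6.765,0.233,81.416,0.559
2,75,30,50,11.767,0.529,107.151,1.688
3,5,70,50,8.202,0.058,85.710,1.091
4,75,70,50,14.558,0.209,127.527,1.820
5,5,50,25,9.917,0.029,53.366,1.640
6,75,50,25,11.334,0.030,72.995,1.090
7,5,50,75,6.750,0.177,79.971,1.444
8,75,50,75,16.424,0.435,130.079,1.354
9,40,30,25,9.979,0.088,74.622,1.205
10,40,70,25,11.020,0.147,88.822,1.860
11,40,30,75,12.399,0.177,124.780,1.876
12,40,70,75,13.833,0.175,130.661,1.757
13,40,50,50,9.583,0.354,93.094,1.651
14,40,50,50,9.124,0.059,91.135,0.195
15,40,50,50,10.270,0.059,95.236,0.335
16,40,50,50,9.589,0.468,91.894,1.178
17,40,50,50,9.842,0.058,95.074,1.603
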