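site,orientation,logQ,a,b,median_m,q95_m
1,E,10.654,8.563,1.802,6.99,15.76
1,N,11.816,5.520,2.121,4.65,9.27
1,W,10.398,8.560,1.756,6.95,16.00
1,S,12.480,9.936,2.046,8.31,16.99
2,E,11.680,8.954,1.817,7.32,16.39
2,N,12.016,8.162,1.897,6.73,14.58
2,W,12.020,8.208,1.904,6.77,14.62
2,S,11.576,5.751,1.940,4.76,10.14
3,W,11.870,6.229,1.948,5.16,10.95
3,S,5.469,7.050,5.491,6.59,8.61
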