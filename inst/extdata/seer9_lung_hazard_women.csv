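"category","area","age_index","age_midpoint","hazard","se"
0,"San Francisco-Oakland",8,37.5,8.55,0.92
0,"San Francisco-Oakland",9,42.5,15.9,1.25
0,"San Francisco-Oakland",10,47.5,37.96,2.09
0,"San Francisco-Oakland",11,52.5,64.57,2.79
0,"San Francisco-Oakland",12,57.5,99.84,3.61
0,"San Francisco-Oakland",13,62.5,138.6,4.42
0,"San Francisco-Oakland",14,67.5,171.63,5.04
0,"San Francisco-Oakland",15,72.5,201.87,5.68
0,"San Francisco-Oakland",16,77.5,198.99,5.93
0,"San Francisco-Oakland",17,82.5,158.51,6.27
0,"San Francisco-Oakland",18,87.5,89.46,4.77
1,"Connecticut",8,37.5,11.65,1.18
1,"Connecticut",9,42.5,28.08,1.89
1,"Connecticut",10,47.5,50.51,2.59
1,"Connecticut",11,52.5,85.15,3.39
1,"Connecticut",12,57.5,124.95,4.14
1,"Connecticut",13,62.5,165.12,4.79
1,"Connecticut",14,67.5,214.92,5.58
1,"Connecticut",15,72.5,239.67,5.9
1,"Connecticut",16,77.5,241.9,6.2
1,"Connecticut",17,82.5,192.88,6.75
1,"Connecticut",18,87.5,96.76,4.74
2,"Detroit",8,37.5,10.63,1.09
2,"Detroit",9,42.5,27.29,1.81
2,"Detroit",10,47.5,58.29,2.79
2,"Detroit",11,52.5,89.58,3.44
2,"Detroit",12,57.5,141.42,4.47
2,"Detroit",13,62.5,184.48,5.18
2,"Detroit",14,67.5,242.01,6.1
2,"Detroit",15,72.5,252.02,6.19
2,"Detroit",16,77.5,245.54,6.5
2,"Detroit",17,82.5,197.33,7.22
2,"Detroit",18,87.5,99.12,5.41
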