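"category","area","age_index","age_midpoint","hazard","se"
0,"San Francisco-Oakland",8,37.5,5.11,0.5
0,"San Francisco-Oakland",9,42.5,14.34,0.92
0,"San Francisco-Oakland",10,47.5,28.9,1.39
0,"San Francisco-Oakland",11,52.5,56.89,2.11
0,"San Francisco-Oakland",12,57.5,99.87,3.1
0,"San Francisco-Oakland",13,62.5,158.96,4.4
0,"San Francisco-Oakland",14,67.5,218.55,5.68
0,"San Francisco-Oakland",15,72.5,253.56,6.6
0,"San Francisco-Oakland",16,77.5,283.49,7.95
0,"San Francisco-Oakland",17,82.5,245.25,9.08
0,"San Francisco-Oakland",18,87.5,171.04,8.72
1,"Connecticut",8,37.5,6.72,0.62
1,"Connecticut",9,42.5,16.58,1.02
1,"Connecticut",10,47.5,39.1,1.69
1,"Connecticut",11,52.5,70.97,2.38
1,"Connecticut",12,57.5,129.2,3.51
1,"Connecticut",13,62.5,203.6,4.82
1,"Connecticut",14,67.5,285.37,6.21
1,"Connecticut",15,72.5,341.7,7.29
1,"Connecticut",16,77.5,381.33,8.65
1,"Connecticut",17,82.5,325.4,9.96
1,"Connecticut",18,87.5,226.73,9.62
2,"Detroit",8,37.5,7.35,0.64
2,"Detroit",9,42.5,19.43,1.12
2,"Detroit",10,47.5,44.07,1.79
2,"Detroit",11,52.5,93.04,2.82
2,"Detroit",12,57.5,154.19,3.91
2,"Detroit",13,62.5,246.4,5.47
2,"Detroit",14,67.5,340.1,7.06
2,"Detroit",15,72.5,402.29,8.25
2,"Detroit",16,77.5,399.53,9.14
2,"Detroit",17,82.5,354.44,11.19
2,"Detroit",18,87.5,236.97,10.93
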