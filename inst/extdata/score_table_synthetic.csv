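sex,tooth,stage,score
M,31,0,0
M,31,A,0.09
M,31,B,1.36
M,31,C,2.62
M,31,D,3.89
M,31,E,5.16
M,31,F,6.42
M,31,G,7.69
M,31,H,9.5
M,32,0,0
M,32,A,0.3
M,32,B,1.7
M,32,C,3.1
M,32,D,4.5
M,32,E,5.9
M,32,F,7.3
M,32,G,8.7
M,32,H,10.5
M,33,0,0
M,33,A,0.57
M,33,B,2.17
M,33,C,3.77
M,33,D,5.37
M,33,E,6.97
M,33,F,8.57
M,33,G,10.17
M,33,H,12
M,34,0,0
M,34,A,0.9
M,34,B,2.7
M,34,C,4.5
M,34,D,6.3
M,34,E,8.1
M,34,F,9.9
M,34,G,11.7
M,34,H,13.5
M,35,0,0
M,35,A,1.24
M,35,B,3.18
M,35,C,5.11
M,35,D,7.04
M,35,E,8.98
M,35,F,10.91
M,35,G,12.84
M,35,H,14.5
M,36,0,0
M,36,A,1.99
M,36,B,4.52
M,36,C,7.06
M,36,D,9.59
M,36,E,12.12
M,36,F,14.66
M,36,G,17.19
M,36,H,19
M,37,0,0
M,37,A,2.6
M,37,B,5.4
M,37,C,8.2
M,37,D,11
M,37,E,13.8
M,37,F,16.6
M,37,G,19.4
M,37,H,21
F,31,0,0
F,31,A,0.1
F,31,B,1.43
F,31,C,2.76
F,31,D,4.1
F,31,E,5.43
F,31,F,6.76
F,31,G,8.1
F,31,H,10
F,32,0,0
F,32,A,0.31
F,32,B,1.78
F,32,C,3.25
F,32,D,4.71
F,32,E,6.18
F,32,F,7.65
F,32,G,9.11
F,32,H,11
F,33,0,0
F,33,A,0.6
F,33,B,2.26
F,33,C,3.93
F,33,D,5.6
F,33,E,7.26
F,33,F,8.93
F,33,G,10.6
F,33,H,12.5
F,34,0,0
F,34,A,0.9
F,34,B,2.7
F,34,C,4.5
F,34,D,6.3
F,34,E,8.1
F,34,F,9.9
F,34,G,11.7
F,34,H,13.5
F,35,0,0
F,35,A,1.2
F,35,B,3.07
F,35,C,4.93
F,35,D,6.8
F,35,E,8.67
F,35,F,10.53
F,35,G,12.4
F,35,H,14
F,36,0,0
F,36,A,1.94
F,36,B,4.4
F,36,C,6.87
F,36,D,9.34
F,36,E,11.8
F,36,F,14.27
F,36,G,16.74
F,36,H,18.5
F,37,0,0
F,37,A,2.54
F,37,B,5.27
F,37,C,8
F,37,D,10.74
F,37,E,13.47
F,37,F,16.2
F,37,G,18.94
F,37,H,20.5
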