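entry_id,F1_N,F2_N,F3_N,F4_N,D1_cm
1,62,50,125,85,71
2,82,62,154,118,54
3,64,52,170,83,66
4,63,64,90,80,67
5,66,75,94,77,55
6,27,24,49,30,70
7,88,69,150,117,68
8,87,86,115,105,58
9,87,79,167,99,57
10,105,92,223,149,65
11,81,79,102,103,68
12,57,45,141,69,67
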