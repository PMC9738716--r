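participant,strawberry,variable,value
1,s1,vas,88
2,s1,vas,84
3,s1,vas,79
4,s1,vas,75
5,s1,vas,73
6,s1,vas,83
7,s1,vas,70
8,s1,vas,74
9,s1,vas,80
10,s1,vas,52
11,s1,vas,88
12,s1,vas,50
13,s1,vas,41
14,s1,vas,58
15,s1,vas,71
16,s1,vas,83
17,s1,vas,57
18,s1,vas,76
19,s1,vas,48
1,s2,vas,77
2,s2,vas,10
3,s2,vas,59
4,s2,vas,78
5,s2,vas,69
6,s2,vas,76
7,s2,vas,70
8,s2,vas,86
9,s2,vas,81
10,s2,vas,39
11,s2,vas,69
12,s2,vas,70
13,s2,vas,18
14,s2,vas,55
15,s2,vas,60
16,s2,vas,73
17,s2,vas,53
18,s2,vas,55
19,s2,vas,64
1,s3,vas,93
2,s3,vas,63
3,s3,vas,89
4,s3,vas,88
5,s3,vas,76
6,s3,vas,6
7,s3,vas,82
8,s3,vas,61
9,s3,vas,74
10,s3,vas,64
11,s3,vas,96
12,s3,vas,74
13,s3,vas,29
14,s3,vas,52
15,s3,vas,83
16,s3,vas,91
17,s3,vas,68
18,s3,vas,48
19,s3,vas,67
1,s4,vas,89
2,s4,vas,56
3,s4,vas,81
4,s4,vas,74
5,s4,vas,77
6,s4,vas,6
7,s4,vas,80
8,s4,vas,56
9,s4,vas,68
10,s4,vas,71
11,s4,vas,96
12,s4,vas,74
13,s4,vas,11
14,s4,vas,48
15,s4,vas,53
16,s4,vas,80
17,s4,vas,47
18,s4,vas,42
19,s4,vas,65
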