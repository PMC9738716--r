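participant,strawberry,variable,value
1,s1,sugar_content,8.3
2,s1,sugar_content,7.7
3,s1,sugar_content,10
4,s1,sugar_content,10.2
5,s1,sugar_content,8.9
6,s1,sugar_content,9.9
7,s1,sugar_content,9.7
8,s1,sugar_content,9.2
9,s1,sugar_content,9.1
10,s1,sugar_content,8.7
11,s1,sugar_content,10.1
12,s1,sugar_content,9.3
13,s1,sugar_content,8.5
14,s1,sugar_content,10.2
15,s1,sugar_content,8.5
16,s1,sugar_content,10.4
17,s1,sugar_content,9.3
18,s1,sugar_content,9.1
19,s1,sugar_content,9.1
1,s2,sugar_content,9.7
2,s2,sugar_content,11.1
3,s2,sugar_content,9
4,s2,sugar_content,10.8
5,s2,sugar_content,11.7
6,s2,sugar_content,10.8
7,s2,sugar_content,10.3
8,s2,sugar_content,9.3
9,s2,sugar_content,9
10,s2,sugar_content,9.2
11,s2,sugar_content,9.5
12,s2,sugar_content,10
13,s2,sugar_content,9.2
14,s2,sugar_content,9.7
15,s2,sugar_content,10.4
16,s2,sugar_content,7.7
17,s2,sugar_content,10.1
18,s2,sugar_content,7
19,s2,sugar_content,8.7
1,s3,sugar_content,14.7
2,s3,sugar_content,9
3,s3,sugar_content,8.8
4,s3,sugar_content,12.7
5,s3,sugar_content,9.7
6,s3,sugar_content,13.4
7,s3,sugar_content,10.8
8,s3,sugar_content,9.4
9,s3,sugar_content,9.9
10,s3,sugar_content,11.6
11,s3,sugar_content,9.7
12,s3,sugar_content,10.8
13,s3,sugar_content,10.4
14,s3,sugar_content,11.8
15,s3,sugar_content,10
16,s3,sugar_content,11.4
17,s3,sugar_content,10.8
18,s3,sugar_content,10.4
19,s3,sugar_content,9.5
1,s4,sugar_content,10.5
2,s4,sugar_content,9.5
3,s4,sugar_content,11.5
4,s4,sugar_content,12
5,s4,sugar_content,9.6
6,s4,sugar_content,10.8
7,s4,sugar_content,11.3
8,s4,sugar_content,8.4
9,s4,sugar_content,9.1
10,s4,sugar_content,10.6
11,s4,sugar_content,8.6
12,s4,sugar_content,10.2
13,s4,sugar_content,9.4
14,s4,sugar_content,11.7
15,s4,sugar_content,8.4
16,s4,sugar_content,10.4
17,s4,sugar_content,8.3
18,s4,sugar_content,9.4
19,s4,sugar_content,10.9
1,s1,acidity,0.76
2,s1,acidity,0.76
3,s1,acidity,0.98
4,s1,acidity,0.66
5,s1,acidity,0.59
6,s1,acidity,0.64
7,s1,acidity,0.58
8,s1,acidity,0.54
9,s1,acidity,0.58
10,s1,acidity,0.59
11,s1,acidity,0.58
12,s1,acidity,0.5
13,s1,acidity,0.57
14,s1,acidity,0.51
15,s1,acidity,0.57
16,s1,acidity,0.78
17,s1,acidity,0.56
18,s1,acidity,0.68
19,s1,acidity,0.75
1,s2,acidity,0.71
2,s2,acidity,0.57
3,s2,acidity,0.58
4,s2,acidity,0.62
5,s2,acidity,0.56
6,s2,acidity,0.7
7,s2,acidity,0.64
8,s2,acidity,0.63
9,s2,acidity,0.58
10,s2,acidity,0.57
11,s2,acidity,0.54
12,s2,acidity,0.59
13,s2,acidity,0.74
14,s2,acidity,0.5
15,s2,acidity,0.51
16,s2,acidity,0.9
17,s2,acidity,0.7
18,s2,acidity,0.47
19,s2,acidity,0.6
1,s3,acidity,0.72
2,s3,acidity,0.6
3,s3,acidity,0.66
4,s3,acidity,0.77
5,s3,acidity,0.65
6,s3,acidity,0.68
7,s3,acidity,0.67
8,s3,acidity,0.52
9,s3,acidity,0.72
10,s3,acidity,0.82
11,s3,acidity,0.48
12,s3,acidity,0.72
13,s3,acidity,0.64
14,s3,acidity,0.66
15,s3,acidity,0.58
16,s3,acidity,0.78
17,s3,acidity,0.72
18,s3,acidity,0.67
19,s3,acidity,0.63
1,s4,acidity,0.61
2,s4,acidity,0.61
3,s4,acidity,0.6
4,s4,acidity,0.63
5,s4,acidity,0.71
6,s4,acidity,0.7
7,s4,acidity,0.62
8,s4,acidity,0.82
9,s4,acidity,0.58
10,s4,acidity,0.58
11,s4,acidity,0.52
12,s4,acidity,0.55
13,s4,acidity,0.59
14,s4,acidity,0.54
15,s4,acidity,0.88
16,s4,acidity,0.69
17,s4,acidity,0.63
18,s4,acidity,0.6
19,s4,acidity,0.63
1,s1,sugar_acid_ratio,10.9
2,s1,sugar_acid_ratio,10.1
3,s1,sugar_acid_ratio,10.2
4,s1,sugar_acid_ratio,15.5
5,s1,sugar_acid_ratio,15.1
6,s1,sugar_acid_ratio,15.5
7,s1,sugar_acid_ratio,16.7
8,s1,sugar_acid_ratio,17
9,s1,sugar_acid_ratio,15.7
10,s1,sugar_acid_ratio,14.7
11,s1,sugar_acid_ratio,17.4
12,s1,sugar_acid_ratio,18.6
13,s1,sugar_acid_ratio,14.9
14,s1,sugar_acid_ratio,20
15,s1,sugar_acid_ratio,14.9
16,s1,sugar_acid_ratio,13.3
17,s1,sugar_acid_ratio,16.6
18,s1,sugar_acid_ratio,13.4
19,s1,sugar_acid_ratio,12.1
1,s2,sugar_acid_ratio,13.7
2,s2,sugar_acid_ratio,19.5
3,s2,sugar_acid_ratio,15.5
4,s2,sugar_acid_ratio,17.4
5,s2,sugar_acid_ratio,20.9
6,s2,sugar_acid_ratio,15.4
7,s2,sugar_acid_ratio,16.1
8,s2,sugar_acid_ratio,14.8
9,s2,sugar_acid_ratio,15.5
10,s2,sugar_acid_ratio,16.1
11,s2,sugar_acid_ratio,17.6
12,s2,sugar_acid_ratio,16.9
13,s2,sugar_acid_ratio,12.4
14,s2,sugar_acid_ratio,19.4
15,s2,sugar_acid_ratio,20.4
16,s2,sugar_acid_ratio,8.6
17,s2,sugar_acid_ratio,14.4
18,s2,sugar_acid_ratio,14.9
19,s2,sugar_acid_ratio,14.5
1,s3,sugar_acid_ratio,20.4
2,s3,sugar_acid_ratio,15
3,s3,sugar_acid_ratio,13.3
4,s3,sugar_acid_ratio,16.5
5,s3,sugar_acid_ratio,14.9
6,s3,sugar_acid_ratio,19.7
7,s3,sugar_acid_ratio,16.1
8,s3,sugar_acid_ratio,18.1
9,s3,sugar_acid_ratio,13.8
10,s3,sugar_acid_ratio,14.1
11,s3,sugar_acid_ratio,20.2
12,s3,sugar_acid_ratio,15
13,s3,sugar_acid_ratio,16.3
14,s3,sugar_acid_ratio,17.9
15,s3,sugar_acid_ratio,17.2
16,s3,sugar_acid_ratio,14.6
17,s3,sugar_acid_ratio,15
18,s3,sugar_acid_ratio,15.5
19,s3,sugar_acid_ratio,15.1
1,s4,sugar_acid_ratio,17.2
2,s4,sugar_acid_ratio,15.6
3,s4,sugar_acid_ratio,19.2
4,s4,sugar_acid_ratio,19
5,s4,sugar_acid_ratio,13.5
6,s4,sugar_acid_ratio,15.4
7,s4,sugar_acid_ratio,18.2
8,s4,sugar_acid_ratio,10.2
9,s4,sugar_acid_ratio,15.7
10,s4,sugar_acid_ratio,18.3
11,s4,sugar_acid_ratio,16.5
12,s4,sugar_acid_ratio,18.5
13,s4,sugar_acid_ratio,15.9
14,s4,sugar_acid_ratio,21.7
15,s4,sugar_acid_ratio,9.5
16,s4,sugar_acid_ratio,15.1
17,s4,sugar_acid_ratio,13.2
18,s4,sugar_acid_ratio,15.7
19,s4,sugar_acid_ratio,17.3
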