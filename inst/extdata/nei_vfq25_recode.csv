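item_id,response,score
1,1,100
1,2,75
1,3,50
1,4,25
1,5,0
2,1,100
2,2,80
2,3,60
2,4,40
2,5,20
2,6,0
3,1,100
3,2,75
3,3,50
3,4,25
3,5,0
4,1,100
4,2,75
4,3,50
4,4,25
4,5,0
5,1,100
5,2,75
5,3,50
5,4,25
5,5,0
5,6,NA
6,1,100
6,2,75
6,3,50
6,4,25
6,5,0
6,6,NA
7,1,100
7,2,75
7,3,50
7,4,25
7,5,0
7,6,NA
8,1,100
8,2,75
8,3,50
8,4,25
8,5,0
8,6,NA
9,1,100
9,2,75
9,3,50
9,4,25
9,5,0
9,6,NA
10,1,100
10,2,75
10,3,50
10,4,25
10,5,0
10,6,NA
11,1,100
11,2,75
11,3,50
11,4,25
11,5,0
11,6,NA
12,1,100
12,2,75
12,3,50
12,4,25
12,5,0
12,6,NA
13,1,100
13,2,75
13,3,50
13,4,25
13,5,0
13,6,NA
14,1,100
14,2,75
14,3,50
14,4,25
14,5,0
14,6,NA
15c,1,100
15c,2,75
15c,3,50
15c,4,25
15c,5,0
16,1,100
16,2,75
16,3,50
16,4,25
16,5,0
16,6,NA
16a,1,100
16a,2,75
16a,3,50
16a,4,25
16a,5,0
16a,6,NA
17,1,0
17,2,25
17,3,50
17,4,75
17,5,100
18,1,0
18,2,25
18,3,50
18,4,75
18,5,100
19,1,0
19,2,25
19,3,50
19,4,75
19,5,100
20,1,0
20,2,25
20,3,50
20,4,75
20,5,100
21,1,0
21,2,25
21,3,50
21,4,75
21,5,100
22,1,0
22,2,25
22,3,50
22,4,75
22,5,100
23,1,0
23,2,25
23,3,50
23,4,75
23,5,100
24,1,0
24,2,25
24,3,50
24,4,75
24,5,100
25,1,0
25,2,25
25,3,50
25,4,75
25,5,100
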