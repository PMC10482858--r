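dataset,hl_left,hl_right,gp_left,gp_right,diff_left,diff_right
1,27.2,26.8,31.5,32.3,4.3,5.4
2,15.6,17.1,11.5,17.0,-4.1,-0.1
3,16.8,16.4,24.7,24.8,7.9,8.4
4,26.3,18.1,34.4,12.9,8.2,-5.2
5,19.8,16.2,12.7,20.8,-7.1,4.6
6,19.2,25.9,16.5,43.0,-2.6,17.1
7,15.2,13.7,9.2,18.0,-6,4.3
8,6.6,9.4,14.0,11.3,7.4,1.9
9,29.3,29.3,38.5,26.5,9.2,-2.8
10,28.0,27.7,35.8,32.0,7.8,4.3
11,3.4,0.5,11.3,11.2,7.9,10.7
12,13.7,9.8,18.8,10.2,5,0.4
13,8.8,19.3,18.6,14.4,9.9,-5
14,5.7,8.8,14.6,9.6,8.9,0.7
15,29.9,29.8,30.2,19.7,0.3,-10.1
16,16.1,16.8,21.9,13.0,5.8,-3.8
17,15.0,19.3,15.6,38.9,0.7,19.6
18,28.8,32.3,32.1,37.1,3.3,4.8
19,12.1,10.0,12.9,9.4,0.8,-0.6
20,2.8,6.6,22.3,10.1,19.5,3.6
21,7.2,5.4,16.3,10.2,9.1,4.7
22,44.0,46.1,49.4,48.9,5.4,2.8
23,3.5,4.1,10.7,12.2,7.2,8.1
24,8.5,9.5,20.3,11.1,11.8,1.6
25,22.0,17.7,18.4,23.8,-3.5,6.1
26,19.7,28.6,12.4,11.3,-7.3,-17.4
27,12.3,10.6,12.4,29.8,0.2,19.2
28,16.1,14.9,13.2,19.8,-2.8,4.9
29,16.9,16.3,26.1,13.4,9.2,-2.8
30,16.3,12.7,10.5,20.1,-5.8,7.4
31,22.3,35.9,10.0,22.7,-12.3,-13.2
32,21.2,20.7,40.3,33.6,19.1,12.9
33,23.2,22.6,30.6,25.4,7.4,2.8
34,6.5,6.4,11.7,9.2,5.2,2.7
35,20.9,20.4,23.8,21.6,3,1.2
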