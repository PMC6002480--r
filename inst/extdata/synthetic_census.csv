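x,y,species,dbh
11.35,9.91,maple,13.1
5.57,7.91,maple,15.3
15.1,35.55,maple,15
59.78,36.15,maple,11.4
26.35,11.9,maple,12.1
38.18,53.3,maple,11.5
26.36,3.62,maple,5.8
3.85,20.74,maple,11.2
29.33,8.27,maple,9
9.55,10.65,maple,8.8
33.52,9.72,maple,20
6.1,15.11,maple,13.2
53.36,44.45,maple,16.1
56.15,34.2,maple,10.6
37.16,6.55,maple,13.7
55.91,42.02,maple,8.5
20.9,39.41,maple,7.1
25.58,0.62,maple,7.9
16.67,32.47,maple,16.9
16.02,27.68,maple,16.4
10.23,13.47,maple,11.5
54.9,44.18,maple,11
20.14,55.58,maple,6.5
8.51,21.73,maple,5.5
6.3,17.03,maple,7.6
58.66,42.65,maple,16.1
35.13,57.07,maple,11.3
54.3,37.4,maple,13
3.27,42.7,maple,8
25.45,55.01,maple,11.2
25.02,0.07,maple,14
1.95,37.78,maple,13.3
36.59,52.79,maple,12.8
4.09,44.22,maple,14.3
58.77,5.58,maple,14.8
33.46,55.22,maple,10.1
11.08,36.78,maple,6.9
6.86,15.58,maple,5.6
27.33,6.52,maple,10.5
55.06,45.16,maple,13.7
4.52,47.48,maple,10.9
21.07,40.48,maple,12.7
2.4,43.38,maple,7.9
41.1,0.44,maple,8.6
33.7,50.83,maple,9.9
30.34,51.72,maple,15.2
18.8,32.83,maple,10.3
58.32,35.31,maple,8.8
56.18,38.6,maple,9.6
32.27,56.32,maple,14
26.91,3.63,maple,9.5
40.23,55.53,maple,9.2
25.41,18.8,maple,10.6
33.97,59.66,maple,9.9
29.06,53.06,maple,8.5
35.06,50.94,maple,8.8
42.27,8.46,maple,7.7
31.32,16.23,maple,12.4
10.86,43.29,maple,11.6
34.26,3.71,maple,10.3
46.29,16.6,linden,15.4
39.94,8.99,linden,17.4
50.63,23.72,linden,13
42.55,23.94,linden,15.4
18.81,13.45,linden,17.5
15.81,21.4,linden,10.2
30.66,6.49,linden,20
35.84,7.65,linden,10.1
20.08,13.25,linden,6.5
50.84,9.25,linden,12.5
19.34,16.46,linden,13.8
13.04,16.44,linden,10.3
43.71,24.62,linden,8.9
25.41,2.97,linden,10.3
34.58,9.58,linden,17.5
38.28,1.67,linden,15.5
23.37,58.98,linden,13.1
17.45,31.37,linden,7.8
48.76,24.81,linden,17.3
45.1,24.46,linden,16.6
12.92,28.66,linden,9.6
26.41,59.63,linden,13.2
52.61,22.75,linden,15.5
30.42,6.12,linden,14.9
37.4,50.94,linden,15.1
42.95,21.01,linden,13.8
37.92,56.34,linden,14.3
48.89,16.43,linden,7.2
46.33,17.05,linden,21.5
37.3,2.51,linden,12.3
15.21,23.22,linden,15
29.66,55.11,linden,7.6
46.17,23.87,linden,11.5
30.98,3.13,linden,16
30.74,3.07,linden,13.6
30.56,2.51,linden,14
12.76,29.39,linden,7.8
50.99,17.57,linden,15
27.28,57.71,linden,11
13.25,26.98,linden,6.4
45.01,2.79,pine,21.5
33.93,2.76,pine,23.4
44.78,48.84,pine,13.1
37.38,4.62,pine,21.2
59.54,49.75,pine,23.9
11.71,59.44,pine,21
58.12,57.81,pine,12.9
37.34,48.45,pine,15.1
42.44,40.15,pine,13.3
3.24,58.1,pine,13.5
9.19,3.49,pine,5.5
6.15,59.02,pine,26.2
44.33,51.45,pine,12.8
42.24,0.24,pine,18.3
48.86,48.36,pine,10
44.21,45.76,pine,21.7
42.45,8.5,pine,11.1
55.75,58.72,pine,14.4
31.64,57.24,pine,19.5
40.85,54.94,pine,23
39.51,6.17,pine,12.9
37.86,51.2,pine,19.6
37.04,56.47,pine,7.9
38.93,6.6,pine,16
41.34,57.44,pine,10
2.84,0.87,pine,10.4
33.42,7.25,pine,18.3
45.76,50.21,pine,14.2
10.5,0.65,pine,17.2
32.34,52.19,pine,12.8
30.94,33.51,fir,46.5
21.81,58.99,fir,33.5
17.04,59.73,fir,31.6
8.56,25.73,fir,22.6
33.19,35.06,fir,25.9
48.64,52.88,fir,33
35.76,30.92,fir,35.4
35.67,31.97,fir,33.2
22.07,4.79,fir,33.7
38.59,30.58,fir,35
1.2,23.49,fir,24.1
20.57,15.74,fir,26.2
53.98,21.25,fir,30.4
20.53,31.2,fir,30.7
8.04,19.05,fir,34.1
52.26,54.11,fir,35.4
49.6,50.7,fir,36.3
31.03,29.65,fir,37.5
28.8,26.43,fir,30.1
28.95,24.24,fir,27
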