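"id","frame","x [nm]","y [nm]","uncertainty [nm]","intensity [photon]","channel","is_fiducial","molecule_id"
1,13,"2815.57","1537.59","6.26","2464.73","647",FALSE,"1"
2,1,"2696.18","1612.29","8.70","471.38","647",FALSE,"2"
3,11,"2734.12","1586.01","7.14","633.66","647",FALSE,"3"
4,36,"2676.60","1467.16","11.55","1455.12","647",FALSE,"4"
5,16,"2811.43","1587.76","11.37","1621.34","647",FALSE,"5"
6,17,"2793.71","1600.94","14.90","953.49","647",FALSE,"5"
7,29,"2725.55","1550.05","10.42","590.30","647",FALSE,"6"
8,7,"2802.00","1551.71","13.58","915.91","647",FALSE,"7"
9,18,"2774.51","1552.53","11.46","3021.90","647",FALSE,"8"
10,23,"2802.92","1560.13","9.97","1399.79","647",FALSE,"8"
11,14,"2842.11","2261.28","9.80","1152.54","647",FALSE,"9"
12,25,"2843.24","2253.28","6.56","688.09","647",FALSE,"9"
13,48,"2819.63","2250.50","10.62","1512.43","647",FALSE,"9"
14,43,"2838.22","2247.34","8.83","982.34","647",FALSE,"9"
15,4,"2838.15","2222.06","16.20","877.79","647",FALSE,"9"
16,2,"2825.76","2205.03","8.40","425.76","647",FALSE,"10"
17,36,"2795.20","2210.53","16.87","1380.44","647",FALSE,"10"
18,44,"2825.80","2198.14","7.79","955.96","647",FALSE,"10"
19,15,"2831.91","2205.54","10.22","869.82","647",FALSE,"10"
20,29,"2854.87","2232.31","11.06","1204.12","647",FALSE,"11"
21,33,"2768.64","2204.58","9.91","1532.92","647",FALSE,"12"
22,24,"2768.80","2214.36","7.64","1178.63","647",FALSE,"12"
23,35,"2798.88","2194.11","10.03","1395.61","647",FALSE,"12"
24,28,"2786.02","2191.26","8.74","1337.32","647",FALSE,"12"
25,49,"2776.16","2203.00","8.96","966.20","647",FALSE,"12"
26,45,"2816.28","2286.35","11.52","1978.26","647",FALSE,"13"
27,1,"2821.82","2299.86","8.11","912.68","647",FALSE,"13"
28,39,"2841.58","2282.45","9.28","1145.05","647",FALSE,"13"
29,22,"2810.81","2307.38","14.75","1198.05","647",FALSE,"13"
30,16,"2813.68","2277.81","8.67","1165.99","647",FALSE,"13"
31,10,"2805.95","2227.13","11.71","599.33","647",FALSE,"14"
32,41,"2888.29","2204.19","9.20","2096.54","647",FALSE,"15"
33,8,"2867.33","2280.99","7.48","587.91","647",FALSE,"16"
34,32,"2809.17","2208.40","11.02","723.08","647",FALSE,"17"
35,34,"2836.33","2217.31","12.63","1439.53","647",FALSE,"17"
36,33,"2812.94","2212.28","11.34","929.52","647",FALSE,"17"
37,20,"2806.16","2156.90","6.30","943.58","647",FALSE,"18"
38,11,"851.44","412.62","11.03","855.41","647",FALSE,"19"
39,43,"857.91","417.23","8.20","1758.60","647",FALSE,"19"
40,39,"851.84","437.41","9.65","687.06","647",FALSE,"19"
41,41,"851.34","431.23","14.39","1201.33","647",FALSE,"19"
42,29,"900.28","357.38","6.65","504.30","647",FALSE,"20"
43,42,"893.23","360.58","10.72","662.58","647",FALSE,"20"
44,26,"887.60","428.71","9.88","867.67","647",FALSE,"21"
45,5,"826.84","435.46","4.85","1039.03","647",FALSE,"22"
46,49,"837.11","484.27","13.54","790.56","647",FALSE,"23"
47,1,"944.75","344.54","5.72","977.64","647",FALSE,"24"
48,17,"867.70","383.81","9.28","512.28","647",FALSE,"25"
49,9,"861.13","385.37","10.55","1079.64","647",FALSE,"25"
50,15,"825.81","386.53","11.37","741.50","647",FALSE,"26"
51,7,"893.91","447.54","8.24","1531.96","647",FALSE,"27"
52,17,"839.45","326.29","7.95","676.74","647",FALSE,"28"
53,21,"844.14","323.34","8.60","1917.27","647",FALSE,"28"
54,5,"825.33","327.03","8.44","569.80","647",FALSE,"28"
55,7,"855.18","330.02","13.69","1345.25","647",FALSE,"28"
56,44,"816.39","429.53","5.03","762.86","647",FALSE,"29"
57,47,"853.00","399.42","5.32","1368.80","647",FALSE,"30"
58,37,"2511.25","1945.91","11.76","967.46","647",FALSE,"31"
59,9,"2514.78","1920.07","11.61","1923.15","647",FALSE,"31"
60,0,"2482.56","1929.61","6.80","667.33","647",FALSE,"32"
61,49,"2378.41","1941.38","12.61","833.56","647",FALSE,"33"
62,14,"2375.06","1945.21","6.75","940.44","647",FALSE,"33"
63,31,"2378.60","1951.44","19.01","1106.90","647",FALSE,"33"
64,34,"2361.91","1951.25","7.26","1313.93","647",FALSE,"33"
65,18,"2454.39","1931.52","8.11","783.88","647",FALSE,"34"
66,0,"2434.80","1932.86","7.80","1178.57","647",FALSE,"34"
67,17,"2443.59","1928.59","8.13","1223.55","647",FALSE,"34"
68,37,"2440.02","1927.49","8.69","1656.02","647",FALSE,"34"
69,15,"2512.12","1965.40","6.10","435.68","647",FALSE,"35"
70,24,"2507.28","1957.15","7.84","749.99","647",FALSE,"36"
71,15,"2504.09","1968.32","9.20","1088.01","647",FALSE,"36"
72,33,"2493.49","1981.34","9.01","993.60","647",FALSE,"36"
73,23,"1868.97","2062.25","7.59","449.57","647",FALSE,"37"
74,45,"1861.50","2069.55","9.86","1368.31","647",FALSE,"37"
75,9,"1858.34","2078.04","13.99","1806.15","647",FALSE,"37"
76,23,"1895.79","2123.50","12.08","641.45","647",FALSE,"38"
77,27,"1790.03","2139.90","6.80","1580.36","647",FALSE,"39"
78,19,"1789.39","2152.34","10.70","629.95","647",FALSE,"39"
79,36,"1985.09","2155.69","8.39","908.94","647",FALSE,"40"
80,46,"1972.39","2172.23","10.11","848.33","647",FALSE,"40"
81,34,"1949.04","2159.50","14.19","1228.30","647",FALSE,"40"
82,45,"1967.61","2154.28","10.91","1159.32","647",FALSE,"40"
83,11,"1961.26","2088.11","10.28","966.57","647",FALSE,"41"
84,9,"1952.18","2085.65","9.06","1166.34","647",FALSE,"41"
85,10,"1957.75","2097.10","13.58","1059.13","647",FALSE,"41"
86,32,"1923.44","2135.83","5.27","678.75","647",FALSE,"42"
87,27,"1941.90","2158.92","12.69","725.00","647",FALSE,"43"
88,26,"1899.09","2093.58","7.16","1502.17","647",FALSE,"44"
89,7,"1913.54","2099.52","16.04","1137.42","647",FALSE,"44"
90,6,"1889.54","2096.42","11.77","1185.28","647",FALSE,"44"
91,19,"392.09","2929.35","9.02","1689.27","647",FALSE,"45"
92,26,"214.38","1440.82","8.66","592.11","647",FALSE,"46"
93,12,"210.37","1447.89","5.36","770.93","647",FALSE,"46"
94,24,"210.99","1453.14","7.84","1296.93","647",FALSE,"46"
95,48,"232.73","1442.27","8.95","1020.13","647",FALSE,"46"
96,6,"217.02","1457.48","6.14","1184.44","647",FALSE,"46"
97,42,"158.89","756.52","6.66","2028.59","647",FALSE,"47"
98,32,"150.89","745.59","7.49","1735.75","647",FALSE,"47"
99,0,"160.30","751.73","9.36","530.29","647",FALSE,"47"
100,39,"1592.61","790.45","10.93","1058.70","647",FALSE,"48"
101,2,"331.76","1640.67","11.03","1400.44","647",FALSE,"49"
102,44,"2232.20","1943.01","10.74","519.15","647",FALSE,"50"
103,42,"2224.94","1947.44","8.77","903.34","647",FALSE,"50"
104,46,"2203.03","1012.09","11.98","901.21","647",FALSE,"51"
105,11,"2650.55","186.34","9.11","874.76","647",FALSE,"52"
106,21,"2654.39","182.66","12.05","933.70","647",FALSE,"52"
107,40,"1553.30","1308.84","19.29","1920.30","647",FALSE,"53"
108,41,"2563.92","2520.64","8.82","1030.22","647",FALSE,"54"
109,47,"2553.91","2518.24","8.66","478.40","647",FALSE,"54"
110,26,"2551.54","2521.55","5.81","355.77","647",FALSE,"54"
111,24,"1339.30","1715.58","14.48","613.22","647",FALSE,"55"
112,16,"470.70","1065.85","5.70","961.79","647",FALSE,"56"
113,11,"1303.57","1625.08","11.92","1705.09","647",FALSE,"57"
114,33,"1339.56","1651.84","11.16","835.09","647",FALSE,"57"
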