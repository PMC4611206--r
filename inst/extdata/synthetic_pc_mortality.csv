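"age","rate"
50,9.86387855766426e-05
51,0.00010579090451993
52,0.000113461610599908
53,0.000121688505626682
54,0.000130511917849216
55,0.000139975099644462
56,0.00015012443954056
57,0.000161009689613454
58,0.000172684209371632
59,0.000185205227324491
60,0.000198634121516564
61,0.000213036720402759
62,0.000228483625539526
63,0.000245050557673766
64,0.000262818727926023
65,0.000281875235887485
66,0.00030231349658229
67,0.000324233698388075
68,0.000347743294159522
69,0.000372957527962379
70,4e-04
71,0.000429003272501687
72,0.000460109519542891
73,0.000493471223982697
74,0.000529251924934975
75,0.000567627019437303
76,0.000608784622247454
77,0.000652926487982152
78,0.000700269000118441
79,0.000751044231705737
80,0.000805501082988191
81,0.000863906501513966
82,0.000926546790712437
83,0.000993729013353927
84,0.00106578249677177
85,0.00114306044722527
86,0.0012259416813172
87,0.00131483248295325
88,0.00141016859494615
89,0.00151241735502751
90,0.00162207998673787
91,0.0017396940564251
92,0.00186583610839525
93,0.00200112449113344
94,0.00214622238844879
95,0.00230184107040229
96,0.00246874337995342
97,0.00264774747241723
98,0.00283973082606265
99,0.00304563454351199
100,0.00326646796502706
101,0.00350331361629634
102,0.00375733251497711
103,0.00402976986200543
104,0.00432196114557251
105,0.00463533868768936
106,0.00497143866543102
107,0.00533190864127831
108,0.00571851563947104
109,0.00613315480796288
110,0.00657785870843882
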