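"age","qx"
50,0.00393669088915127
51,0.00430504474503213
52,0.00471279477087083
53,0.00516413557510098
54,0.0056637041047678
55,0.00621662532417666
56,0.00682856239018426
57,0.0075057717158592
58,0.00825516333613885
59,0.0090843670089652
60,0.0100018045020341
61,0.0110167685272663
62,0.0121395087905457
63,0.0133813256208403
64,0.014754671627629
65,0.0162732618050141
66,0.0179521924506115
67,0.0198080691918936
68,0.0218591443055886
69,0.0241254633691361
70,0.0266290210876049
71,0.0293939258836459
72,0.0324465725086786
73,0.0358158215149734
74,0.0395331839025166
75,0.0436330086007022
76,0.0481526696394661
77,0.0531327488812091
78,0.0586172089951442
79,0.0646535499292104
80,0.0712929404404815
81,0.078590314253343
82,0.0866044180998228
83,0.0953977962404561
84,0.10503669306242
85,0.115590852020822
86,0.127133185576321
87,0.13973928697886
88,0.153486750904724
89,0.168454266304029
90,0.184720441693929
91,0.20236232100597
92,0.221453547590352
93,0.242062135908468
94,0.2642478158299
95,0.288058924529237
96,0.313528837190932
97,0.340671951660566
98,0.369479275442341
99,0.399913707480798
100,0.431905162949551
101,0.465345756854264
102,0.50008534018875
103,0.53592776697631
104,0.572628355047497
105,0.609893077273269
106,0.647380068211355
107,0.684704034347561
108,0.721444091505547
109,0.757155396786311
110,0.791384674313403
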