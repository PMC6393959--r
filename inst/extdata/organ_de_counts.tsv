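organ	duration_h	n_down	n_up
cotyledons	3	855	1286
hypocotyl	3	1238	937
leaf	3	765	1351
flower	3	352	670
young_flower	3	603	560
seeds	3	1112	1142
cotyledons	27	2885	3092
hypocotyl	27	3546	2699
leaf	27	3580	3287
flower	27	1350	961
young_flower	27	2388	2134
seeds	27	1766	1327
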