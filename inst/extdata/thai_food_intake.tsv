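food	g_per_day	sd_g_per_day	vmh_status
Rice	262.53	46.01	Matched
Dumpling	68.12	12.58	Unmatched
Sandwich	60.12	7.80	Matched
Sweet potato	69.12	10.23	Matched
Peanuts	54.78	7.50	Matched
Cowpeas	33.33	5.41	Matched
Mushrooms	29.96	4.63	Matched
Pickled cabbage	24.67	4.07	Matched
Watermelon	202.27	29.06	Matched
Snacks, banana chips	25.00	4.20	Matched
Egg	55.42	4.94	Matched
Pork	31.02	5.45	Matched
Pork meatball	62.75	11.53	Unmatched
Fish, tilapia	64.43	12.60	Matched
Fish, mackerel	30.37	5.23	Matched
Insect, cricket	22.26	4.45	Unmatched
Milk	241.01	32.73	Matched
Ice cream	62.36	4.65	Matched
Beer	454.17	301.01	Matched
Snacks, potato chips	22.88	5.45	Matched
Thai dessert (Khao Tom Mud)	88.66	11.42	Unmatched
Sugar	6.37	1.11	Matched
Oil, palm	9.81	1.22	Matched
Fish sauce	5.37	0.78	Unmatched
Chicken essence	47.57	4.87	Unmatched
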