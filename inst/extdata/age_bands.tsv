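band	total	male	female
60-69	1787022	841369	945653
70-79	1284756	606310	678446
80-89	543220	231466	311754
90-99	164758	55043	109715
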