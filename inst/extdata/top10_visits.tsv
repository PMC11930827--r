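disease	total	male	female
Hypertension	2448548	1142288	1306260
Chronic ischaemic heart disease	1476396	637315	839081
Type 2 diabetes mellitus	943812	465184	478628
Lipoprotein metabolism disorders	823572	329847	493725
Gastritis	744880	311084	433796
Sleep disorders	667676	272915	394761
Conjunctivitis	518629	195735	322894
Intestinal disorders	513921	218230	295691
Bronchitis	458076	199803	258273
Respiratory disorders	430433	200616	229817
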