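# 38-disease chronic panel of the Shanghai comorbidity study.
# Each entry: merged code, display name, raw ICD-10 source codes/prefixes,
# and whether the disease is one of the five most prevalent index diseases.
# The study documents two source mappings explicitly (ee03 <- E03.8 + E03.9,
# ii2520 <- I25 + I20); the remaining source sets are reconstructed from the
# merged-code names and are configuration, not study data.
seed: 20230601
panel:
  - {code: i10,    name: "Hypertension",                              top5: true,  sources: [I10]}
  - {code: ii2520, name: "Chronic ischaemic heart disease",           top5: true,  sources: [I25, I20]}
  - {code: ee1114, name: "Type 2 diabetes mellitus",                  top5: true,  sources: [E11, E14]}
  - {code: kk29,   name: "Gastritis",                                 top5: true,  sources: [K29]}
  - {code: e78,    name: "Lipoprotein metabolism disorders",          top5: true,  sources: [E78]}
  - {code: ee03,   name: "Hypothyroidism",                            sources: [E03.8, E03.9]}
  - {code: ee04,   name: "Non-toxic diffuse goiter",                  sources: [E04]}
  - {code: g47_0,  name: "Sleep disorders",                           sources: [G47.0]}
  - {code: g47_3,  name: "Sleep apnea",                               sources: [G47.3]}
  - {code: i21,    name: "Acute myocardial infarction",               sources: [I21]}
  - {code: i49,    name: "Cardiac arrhythmia",                        sources: [I49]}
  - {code: i63,    name: "Cerebral infarction",                       sources: [I63]}
  - {code: ii67,   name: "Cerebrovascular disease",                   sources: [I67, I69]}
  - {code: j31_0,  name: "Chronic rhinitis",                          sources: [J31.0]}
  - {code: j31_2,  name: "Chronic pharyngitis",                       sources: [J31.2]}
  - {code: jj4042, name: "Bronchitis",                                sources: [J40, J41, J42]}
  - {code: k21,    name: "GERD with esophagitis",                     sources: [K21]}
  - {code: k52_9,  name: "Non-infective gastroenteritis and colitis", sources: [K52.9]}
  - {code: k59_0,  name: "Constipation",                              sources: [K59.0]}
  - {code: k59_1,  name: "Functional diarrhea",                       sources: [K59.1]}
  - {code: k63_5,  name: "Polyps of the colon",                       sources: [K63.5]}
  - {code: k76_0,  name: "Non-alcoholic fatty liver disease",         sources: [K76.0]}
  - {code: l30_9,  name: "Dermatitis",                                sources: [L30.9]}
  - {code: m13,    name: "Arthritis",                                 sources: [M13]}
  - {code: m81,    name: "Osteoporosis",                              sources: [M81]}
  - {code: nn18,   name: "Chronic kidney disease",                    sources: [N18, N19]}
  - {code: r42,    name: "Dizziness and giddiness",                   sources: [R42]}
  - {code: f41,    name: "Anxiety disorders",                         sources: [F41]}
  - {code: f48,    name: "Neurotic disorders",                        sources: [F48]}
  - {code: i48,    name: "Atrial fibrillation and flutter",           sources: [I48]}
  - {code: i50,    name: "Heart failure",                             sources: [I50]}
  - {code: i70,    name: "Atherosclerosis",                           sources: [I70]}
  - {code: j44,    name: "Chronic obstructive pulmonary disease",     sources: [J44]}
  - {code: k25,    name: "Gastric ulcer",                             sources: [K25]}
  - {code: me1079, name: "Hyperuricemia",                             sources: [M10, E79]}
  - {code: m17,    name: "Gonarthrosis",                              sources: [M17]}
  - {code: m47,    name: "Spondylosis",                               sources: [M47]}
  - {code: n95,    name: "(Peri-)menopausal disorders",               sources: [N95]}
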