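code,label
A09,Infectious gastroenteritis and colitis
B34.9,Viral infection unspecified
E11.9,Type 2 diabetes mellitus without complications
E66.9,Obesity unspecified
E78.5,Hyperlipidaemia unspecified
F32.9,Depressive episode unspecified
G43.9,Migraine unspecified
I10,Essential primary hypertension
I21.9,Acute myocardial infarction unspecified
I48.9,Atrial fibrillation and flutter unspecified
I50.9,Heart failure unspecified
J18.9,Pneumonia unspecified organism
J44.9,Chronic obstructive pulmonary disease unspecified
J45.9,Asthma unspecified
K29.7,Gastritis unspecified
K57.9,Diverticular disease of intestine unspecified
K70.3,Alcoholic cirrhosis of liver
K85.9,Acute pancreatitis unspecified
K92.2,Gastrointestinal haemorrhage unspecified
M54.5,Low back pain
N18.9,Chronic kidney disease unspecified
N39.0,Urinary tract infection site not specified
R07.4,Chest pain unspecified
U07.1,COVID-19 virus identified
Z51.1,Encounter for antineoplastic chemotherapy
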