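DX,DX_TYPE,DESCRIPTION
E11.9,10,Type 2 diabetes mellitus without complications
I10,10,Essential (primary) hypertension
E78.5,10,Hyperlipidemia unspecified
J06.9,10,Acute upper respiratory infection
M54.5,10,Low back pain
F41.9,10,Anxiety disorder unspecified
F32.9,10,Major depressive disorder single episode
J45.909,10,Unspecified asthma uncomplicated
N39.0,10,Urinary tract infection site not specified
K21.9,10,Gastro-esophageal reflux disease without esophagitis
I25.10,10,Atherosclerotic heart disease of native coronary artery
E66.9,10,Obesity unspecified
J44.9,10,Chronic obstructive pulmonary disease unspecified
G47.33,10,Obstructive sleep apnea
M17.9,10,Osteoarthritis of knee unspecified
R07.9,10,Chest pain unspecified
R10.9,10,Unspecified abdominal pain
I48.91,10,Unspecified atrial fibrillation
N18.3,10,Chronic kidney disease stage 3
D64.9,10,Anemia unspecified
Z00.00,10,General adult medical examination
R51.9,10,Headache unspecified
L30.9,10,Dermatitis unspecified
H66.90,10,Otitis media unspecified
B34.9,10,Viral infection unspecified
S93.401A,10,Sprain of ankle initial encounter
250.00,09,Diabetes mellitus type II without complication
401.9,09,Essential hypertension unspecified
272.4,09,Hyperlipidemia other and unspecified
465.9,09,Acute upper respiratory infection
724.2,09,Lumbago
300.00,09,Anxiety state unspecified
311,09,Depressive disorder not elsewhere classified
493.90,09,Asthma unspecified
599.0,09,Urinary tract infection site not specified
530.81,09,Esophageal reflux
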