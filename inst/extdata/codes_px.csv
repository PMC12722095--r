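PX,PX_TYPE,DESCRIPTION
99213,CH,Office outpatient visit established patient level 3
99214,CH,Office outpatient visit established patient level 4
99203,CH,Office outpatient visit new patient level 3
99283,CH,Emergency department visit level 3
99285,CH,Emergency department visit level 5
99223,CH,Initial hospital care level 3
99232,CH,Subsequent hospital care level 2
99238,CH,Hospital discharge day management
36415,CH,Collection of venous blood by venipuncture
80053,CH,Comprehensive metabolic panel
85025,CH,Complete blood count with differential
93000,CH,Electrocardiogram complete
71046,CH,Radiologic examination chest 2 views
73721,CH,MRI any joint of lower extremity
70450,CH,CT head or brain without contrast
45378,CH,Colonoscopy flexible diagnostic
43239,CH,Esophagogastroduodenoscopy with biopsy
29881,CH,Knee arthroscopy with meniscectomy
90471,CH,Immunization administration
90686,CH,Influenza virus vaccine quadrivalent
0DB64Z3,10,Excision of stomach percutaneous approach
0SRC0J9,10,Replacement of right knee joint with synthetic substitute
81.54,09,Total knee replacement
45.23,09,Colonoscopy
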