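LAB_LOINC,COMPONENT,UNITS,LOW,HIGH
2345-7,Glucose,mg/dL|mmol/L,50,400
2160-0,Creatinine,mg/dL|umol/L,0.3,10
718-7,Hemoglobin,g/dL|g/L,5,20
4548-4,Hemoglobin A1c,%,3.5,18
2823-3,Potassium,mmol/L|mEq/L,2.5,7.5
2951-2,Sodium,mmol/L|mEq/L,115,165
3094-0,Urea nitrogen,mg/dL|mmol/L,2,100
1742-6,ALT,U/L,5,1500
1920-8,AST,U/L,5,1500
6768-6,Alkaline phosphatase,U/L,20,1200
2093-3,Cholesterol total,mg/dL|mmol/L,80,500
2571-8,Triglycerides,mg/dL|mmol/L,30,2000
13457-7,LDL cholesterol calculated,mg/dL|mmol/L,20,400
2085-9,HDL cholesterol,mg/dL|mmol/L,10,150
6690-2,Leukocytes,10*3/uL,1,100
777-3,Platelets,10*3/uL,10,1500
789-8,Erythrocytes,10*6/uL,2,8
2885-2,Protein total,g/dL|g/L,4,12
1751-7,Albumin,g/dL|g/L,1.5,6
1975-2,Bilirubin total,mg/dL|umol/L,0.1,30
2532-0,Lactate dehydrogenase,U/L,50,2500
2276-4,Ferritin,ng/mL|ug/L,5,5000
3016-3,TSH,mIU/L,0.01,100
2132-9,Vitamin B12,pg/mL|pmol/L,100,2000
1988-5,C-reactive protein,mg/L|mg/dL,0.1,400
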