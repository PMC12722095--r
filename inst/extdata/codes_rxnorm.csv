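RXNORM_CUI,TTY,NAME
197361,SCD,amlodipine 5 MG Oral Tablet
197381,SCD,atenolol 50 MG Oral Tablet
198440,SCD,simvastatin 20 MG Oral Tablet
310965,SCD,ibuprofen 200 MG Oral Tablet
313782,SCD,metformin hydrochloride 500 MG Oral Tablet
308136,SCD,amoxicillin 500 MG Oral Capsule
312961,SCD,lisinopril 10 MG Oral Tablet
197517,SCD,clarithromycin 500 MG Oral Tablet
311354,SCD,levothyroxine sodium 0.05 MG Oral Tablet
855332,SCD,warfarin sodium 5 MG Oral Tablet
617314,SBD,atorvastatin 20 MG Oral Tablet [Lipitor]
104490,SBD,sertraline 50 MG Oral Tablet [Zoloft]
206765,SBD,insulin glargine 100 UNT/ML Injectable Solution [Lantus]
749783,GPCK,{21 (ethinyl estradiol / norethindrone) } Pack
747192,GPCK,{7 (azithromycin 250 MG) } Pack
831533,BPCK,{12 (methylprednisolone 4 MG) } Pack [Medrol Dosepak]
5640,IN,ibuprofen
6809,IN,metformin
29046,IN,lisinopril
36567,IN,simvastatin
10582,IN,levothyroxine
11289,IN,warfarin
161,IN,acetaminophen
723,IN,amoxicillin
203150,BN,Lipitor
58930,BN,Zoloft
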