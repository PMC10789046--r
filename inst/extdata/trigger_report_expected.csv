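"trigger_id","module","positive_triggers","ades","ppv"
"L1","laboratory",1,0,"0.00%"
"L2","laboratory",0,0,"-"
"L3","laboratory",0,0,"-"
"L4","laboratory",0,0,"-"
"L5","laboratory",17,0,"0.00%"
"L6","laboratory",4,0,"0.00%"
"L7","laboratory",0,0,"-"
"L8","laboratory",0,0,"-"
"L9","laboratory",3,0,"0.00%"
"L10","laboratory",1,0,"0.00%"
"L11","laboratory",2,1,"50.00%"
"L12","laboratory",7,0,"0.00%"
"M1","medication",0,0,"-"
"M2","medication",1,1,"100.00%"
"M3","medication",0,0,"-"
"M4","medication",0,0,"-"
"M5","medication",0,0,"-"
"M6","medication",36,2,"5.56%"
"M7","medication",0,0,"-"
"M8","medication",1,1,"100.00%"
"M9","medication",15,0,"0.00%"
"S1","symptom",3,2,"66.67%"
"S2","symptom",10,6,"60.00%"
"S3","symptom",11,11,"100.00%"
"S4","symptom",0,0,"-"
"S5","symptom",4,3,"75.00%"
"S6","symptom",7,5,"71.43%"
"S7","symptom",0,0,"-"
"S8","symptom",0,0,"-"
"S9","symptom",0,0,"-"
"S10","symptom",2,2,"100.00%"
"S11","symptom",9,9,"100.00%"
"S12","symptom",0,0,"-"
"S13","symptom",4,4,"100.00%"
"S14","symptom",0,0,"-"
"O1","outcome",2,2,"100.00%"
"O2","outcome",3,0,"0.00%"
"O3","outcome",11,7,"63.64%"
"O4","outcome",0,0,"-"
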