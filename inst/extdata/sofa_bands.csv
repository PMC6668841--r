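component,variable,low,high,vaso,points
respiration,pao2_fio2_ratio,400,,,0
respiration,pao2_fio2_ratio,300,400,,1
respiration,pao2_fio2_ratio,200,300,,2
respiration,pao2_fio2_ratio,100,200,,3
respiration,pao2_fio2_ratio,,100,,4
coagulation,platelets,150,,,0
coagulation,platelets,100,150,,1
coagulation,platelets,50,100,,2
coagulation,platelets,20,50,,3
coagulation,platelets,,20,,4
liver,bilirubin,,1.2,,0
liver,bilirubin,1.2,2,,1
liver,bilirubin,2,6,,2
liver,bilirubin,6,12,,3
liver,bilirubin,12,,,4
cardiovascular,mean_arterial_pressure,70,,0,0
cardiovascular,mean_arterial_pressure,,70,0,1
cardiovascular,mean_arterial_pressure,70,,1,3
cardiovascular,mean_arterial_pressure,,70,1,4
cns,gcs,15,,,0
cns,gcs,13,15,,1
cns,gcs,10,13,,2
cns,gcs,6,10,,3
cns,gcs,,6,,4
renal,creatinine,,1.2,,0
renal,creatinine,1.2,2,,1
renal,creatinine,2,3.5,,2
renal,creatinine,3.5,5,,3
renal,creatinine,5,,,4
renal_urine,urine_output_24h,500,,,0
renal_urine,urine_output_24h,200,500,,3
renal_urine,urine_output_24h,,200,,4
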