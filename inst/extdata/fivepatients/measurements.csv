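patient_id,date,variable,value
P1,2023-01-01,creatinine,1.0
P1,2023-01-02,creatinine,1.1
P1,2023-01-03,creatinine,1.0
P1,2023-01-04,creatinine,1.05
P1,2023-01-05,creatinine,1.0
P1,2023-01-06,creatinine,1.1
P1,2023-01-01,heart_rate,82
P1,2023-01-05,heart_rate,90
P2,2023-01-02,creatinine,1.0
P2,2023-01-03,creatinine,1.0
P2,2023-01-04,creatinine,1.1
P2,2023-01-05,creatinine,1.2
P2,2023-01-06,creatinine,1.55
P2,2023-01-07,creatinine,1.6
P2,2023-01-02,heart_rate,95
P2,2023-01-05,heart_rate,110
P3,2023-01-03,creatinine,0.8
P3,2023-01-04,creatinine,0.85
P3,2023-01-05,creatinine,0.8
P3,2023-01-06,creatinine,0.9
P3,2023-01-03,heart_rate,70
P5,2023-01-10,creatinine,1.2
P5,2023-01-10,heart_rate,100
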