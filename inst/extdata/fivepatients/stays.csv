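patient_id,admit_date,discharge_date
P1,2023-01-01,2023-01-06
P2,2023-01-02,2023-01-08
P3,2023-01-03,2023-01-07
P4,2023-01-04,2023-01-09
P5,2023-01-10,2023-01-10
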