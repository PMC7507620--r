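patient_id,date,drug_id
P1,2023-01-01,ampicillin
P1,2023-01-01,furosemide
P1,2023-01-02,furosemide
P2,2023-01-02,ibuprofen
P2,2023-01-02,vancomycin
P2,2023-01-03,ibuprofen
P2,2023-01-03,vancomycin
P2,2023-01-04,ibuprofen
P3,2023-01-04,furosemide
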