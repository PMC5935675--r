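ae_name,grade1,grade2,grade3,grade4
Alanine aminotransferase increased,1,2,0,0
Alkaline phosphatase increased,1,2,1,0
Anemia,1,2,3,0
Anorexia,2,3,0,0
Ascites,0,0,1,0
Aspartate aminotransferase increased,1,1,2,0
Constipation,2,1,0,0
Cough,4,1,0,0
Dyspnea,4,2,0,0
Edema limbs,1,2,0,0
Fatigue,8,4,0,0
GGT increased,0,0,1,0
Hyponatremia,0,0,1,0
Nausea,2,1,0,0
Neutrophil count decreased,0,1,2,0
Pain,0,4,0,0
Peripheral sensory neuropathy,3,0,0,0
Platelet count decreased,2,1,0,0
Pleural effusion,0,3,0,0
Syncope,0,0,1,0
Vascular disorders - other,0,0,0,1
White blood cell decreased,0,0,1,0
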