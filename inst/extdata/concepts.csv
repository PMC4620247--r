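system,code,display
MedDRA,10051592,Acute coronary syndrome
MedDRA,10000891,Acute myocardial infarction
MedDRA,10002388,Unstable angina pectoris
MedDRA,10007559,Congestive heart failure
MedDRA,10010265,Congestive cardiomyopathy
MedDRA,10067585,Type 2 diabetes mellitus
MedDRA,10012601,Diabetes mellitus
MedDRA,10020772,Hypertension
MedDRA,10003658,Atrial fibrillation
MedDRA,10008479,Cerebrovascular accident
MedDRA,10011078,Cough
MedDRA,10013968,Dyspnoea
MedDRA,10016558,Fatigue
MedDRA,10019211,Headache
MedDRA,10062237,Renal impairment
MedDRA,10002383,Angina pectoris
MedDRA,10003553,Asthma
MedDRA,10012378,Depression
MedDRA,10002855,Anxiety
MedDRA,10020538,Hypercholesterolaemia
ICD9CM,410.0,Acute myocardial infarction of anterolateral wall
ICD9CM,410.1,Acute myocardial infarction of other anterior wall
ICD9CM,410.9,Acute myocardial infarction of unspecified site
ICD9CM,411.1,Intermediate coronary syndrome
ICD9CM,428.0,Congestive heart failure unspecified
ICD9CM,250.00,Diabetes mellitus type II without mention of complication
ICD9CM,401.9,Unspecified essential hypertension
ICD9CM,272.4,Other and unspecified hyperlipidemia
ICD9CM,427.31,Atrial fibrillation
ICD9CM,434.91,Cerebral artery occlusion unspecified with cerebral infarction
ICD9CM,486,Pneumonia organism unspecified
ICD9CM,585.9,Chronic kidney disease unspecified
ICD9CM,280.9,Iron deficiency anemia unspecified
ICD9CM,530.81,Esophageal reflux
ICD9CM,715.90,Osteoarthrosis unspecified whether generalized or localized
ICD9CM,300.00,Anxiety state unspecified
ICD9CM,311,Depressive disorder not elsewhere classified
ICD9CM,493.90,Asthma unspecified
ICD9CM,413.9,Other and unspecified angina pectoris
ICD9CM,272.0,Pure hypercholesterolemia
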