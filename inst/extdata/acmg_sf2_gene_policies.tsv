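gene_symbol	inheritance	ep_eligible	condition
ACTA2	AD	true	Familial thoracic aortic aneurysm and dissection
ACTC1	AD	true	Hypertrophic cardiomyopathy, dilated cardiomyopathy
APC	AD	true	Familial adenomatous polyposis
APOB	AD	false	Familial hypercholesterolemia
ATP7B	AR	true	Wilson disease
BMPR1A	AD	true	Juvenile polyposis syndrome
BRCA1	AD	true	Hereditary breast and ovarian cancer
BRCA2	AD	true	Hereditary breast and ovarian cancer
CACNA1S	AD	false	Malignant hyperthermia susceptibility
COL3A1	AD	true	Ehlers-Danlos syndrome, vascular type
DSC2	AD	true	Arrhythmogenic right ventricular cardiomyopathy
DSG2	AD	true	Arrhythmogenic right ventricular cardiomyopathy
DSP	AD	true	Arrhythmogenic right ventricular cardiomyopathy
FBN1	AD	true	Marfan syndrome, Loeys-Dietz syndromes, familial thoracic aortic aneurysms and dissections
GLA	XL	true	Fabry disease
KCNH2	AD	true	Long QT syndrome
KCNQ1	AD	true	Long QT syndrome
LDLR	AD	true	Familial hypercholesterolemia
LMNA	AD	true	Dilated cardiomyopathy
MEN1	AD	true	Multiple endocrine neoplasia type 1
MLH1	AD	true	Lynch syndrome
MSH2	AD	true	Lynch syndrome
MSH6	AD	true	Lynch syndrome
MUTYH	AR	true	MUTYH-associated polyposis
MYBPC3	AD	true	Hypertrophic cardiomyopathy, dilated cardiomyopathy
MYH11	AD	true	Familial thoracic aortic aneurysm and dissection
MYH7	AD	true	Hypertrophic cardiomyopathy, dilated cardiomyopathy
MYL2	AD	true	Hypertrophic cardiomyopathy
MYL3	AD	true	Hypertrophic cardiomyopathy
NF2	AD	true	Neurofibromatosis type 2
OTC	XL	true	Ornithine transcarbamylase deficiency
PCSK9	AD	false	Familial hypercholesterolemia
PKP2	AD	true	Arrhythmogenic right ventricular cardiomyopathy
PMS2	AD	true	Lynch syndrome
PRKAG2	AD	true	Hypertrophic cardiomyopathy
PTEN	AD	true	PTEN hamartoma tumor syndrome
RB1	AD	true	Retinoblastoma
RET	AD	true	Multiple endocrine neoplasia type 2, familial medullary thyroid cancer
RYR1	AD	false	Malignant hyperthermia susceptibility
RYR2	AD	false	Catecholaminergic polymorphic ventricular tachycardia
SCN5A	AD	true	Long QT syndrome, Brugada syndrome
SDHAF2	AD	true	Hereditary paraganglioma-pheochromocytoma syndrome
SDHB	AD	true	Hereditary paraganglioma-pheochromocytoma syndrome
SDHC	AD	true	Hereditary paraganglioma-pheochromocytoma syndrome
SDHD	AD	true	Hereditary paraganglioma-pheochromocytoma syndrome
SMAD3	AD	true	Loeys-Dietz syndrome
SMAD4	AD	true	Juvenile polyposis syndrome
STK11	AD	true	Peutz-Jeghers syndrome
TGFBR1	AD	true	Loeys-Dietz syndrome
TGFBR2	AD	true	Loeys-Dietz syndrome
TMEM43	AD	true	Arrhythmogenic right ventricular cardiomyopathy
TNNI3	AD	true	Hypertrophic cardiomyopathy
TNNT2	AD	true	Hypertrophic cardiomyopathy, dilated cardiomyopathy
TP53	AD	true	Li-Fraumeni syndrome
TPM1	AD	true	Hypertrophic cardiomyopathy
TSC1	AD	true	Tuberous sclerosis complex
TSC2	AD	true	Tuberous sclerosis complex
VHL	AD	true	Von Hippel-Lindau syndrome
WT1	AD	true	WT1-related Wilms tumor
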