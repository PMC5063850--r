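organ,morphology,human_relevant,rationale
hsyst,leu,FALSE,"mononuclear cell leukemia, common spontaneous tumor of aged rats"
ut,polyp,FALSE,"endometrial stromal polyps, common spontaneous tumor of aged rats"
pan,*,FALSE,"pancreatic acinar tumors, rat-specific secretagogue/trophic mechanisms"
islet,*,FALSE,"islet cell neoplasia, not predictive for humans"
adr,*,FALSE,"adrenal medullary pheochromocytoma, rodent-specific Ca2+/catecholamine mechanism"
tes,*,FALSE,"Leydig (interstitial) cell tumors, rat LH axis not operative in man"
thyr,*,FALSE,thyroid follicular tumors secondary to hepatic enzyme induction and T3/T4 clearance
pit,*,FALSE,"adenohypophysis tumors, very high spontaneous incidence in aged rats"
stom,*,FALSE,forestomach tumors; humans have no forestomach
li,*,FALSE,"hepatocellular tumors of non-genotoxic origin, rodent hepatotrophic responses"
mam,*,FALSE,"mammary tumors, high spontaneous incidence driven by rodent prolactin axis"
UGT,*,FALSE,urinary bladder/urogenital tumors via rat urine crystallization
*,ad,FALSE,"benign adenoma, common spontaneous finding in aged rats"
*,fad,FALSE,benign fibroadenoma
*,polyp,FALSE,benign polyp
*,pap,FALSE,benign papilloma
*,fibr,FALSE,benign fibroma
*,leio,FALSE,"benign leiomyoma (mesovarian), rat-specific beta-adrenergic response"
*,bhaem,FALSE,benign hemangioma
*,gca,FALSE,benign granulosa cell tumor
*,SCP,FALSE,benign squamous cell papilloma
*,schwan,FALSE,benign schwannoma
*,lip,FALSE,benign lipoma
*,bthym,FALSE,benign thymoma
*,bpha,FALSE,benign pheochromocytoma
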