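code,name,behavior,note
ac,adenocarcinoma/carcinoma,malignant,
ad,adenoma,benign,
ad/ca,adenoma/carcinoma,unspecified,mixed benign and malignant report
astr,astrocytoma,malignant,
bhaem,"hemangioma, benign",benign,
bpha,"pheochromocytoma, benign",benign,
bthym,"thymoma, benign",benign,
ca,carcinoma,malignant,
fad,fibroadenoma,benign,
fibr,fibroma,benign,
gca,granulosa cell tumor,benign,inferred benign; low confidence
gli,glioma,malignant,
leio,leiomyoma,benign,
leu,leukemia,malignant,
lip,lipoma,benign,
lymph,lymphoma,malignant,
mel,melanoma,malignant,
most,osteosarcoma,malignant,inferred from context; low confidence
mpha,"pheochromocytoma, malignant",malignant,
pap,papilloma,benign,
polyp,polyp (endometrial stromal),benign,
sar,sarcoma,malignant,
SCC,squamous cell carcinoma,malignant,
SCP,squamous cell papilloma,benign,
schwan,schwannoma,benign,
tu,"tumor, unspecified behavior",unspecified,
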