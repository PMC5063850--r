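code,name,system,note
UGT,urogenital tract (urinary bladder),urinary,
adr,adrenal gland,endocrine,
bm,bone marrow,hematopoietic,
bo,bone,skeletal,
br,brain,nervous,
ce,cecum,digestive,inferred from context; low confidence
col,colon,digestive,
epi,epididymis,reproductive,
gon,gonads,reproductive,
hrt,heart,cardiovascular,
hsyst,hematopoietic system,hematopoietic,
int,intestine,digestive,
islet,pancreatic islets,endocrine,
kid,kidney,urinary,
li,liver,digestive,
ln,lymph node,lymphoid,
lu,lung,respiratory,
mam,mammary gland,reproductive,
many,multiple organs,systemic,collective token used for widespread organ-weight changes
mes,mesentery,digestive,
nose,nasal cavity,respiratory,
oral,oral mucosa,digestive,
ova,ovary,reproductive,
pan,"pancreas, exocrine",digestive,
parath,parathyroid gland,endocrine,
pit,pituitary gland,endocrine,
pros,prostate,reproductive,
sgl,salivary gland,digestive,
sk,skin,integumentary,spelling variant of skin
skin,skin,integumentary,
soft t,soft tissue,connective,
spl,spleen,lymphoid,
stom,stomach (forestomach),digestive,
tes,testis,reproductive,
thy,thymus,lymphoid,spelling variant of thym
thym,thymus,lymphoid,
thyr,thyroid gland,endocrine,
unsp,organ not specified,unspecified,subchronic lesion site not recoverable from source
ut,uterus,reproductive,
vag,vagina,reproductive,
zymgl,Zymbal's gland,integumentary,
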