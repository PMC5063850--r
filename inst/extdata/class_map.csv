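mode_of_action_pattern,class_id
"ab, fluoroquinolone",ab_fluoroquinolones
"ab, remaining, bactericidal",ab_remaining
"af, conazole derivative",af_conazoles
"af, remaining, allylamine derivative",af_remaining
"af, remaining, benzimidazole",af_remaining
"ai, cox2 inhibitor",ai_cox2_inhibitors
"ai, nsaid",ai_nsaids
"am, remaining, antimalarial",am_remaining
"am, remaining, antiparasite",am_remaining
av,av_antivirals
"av, ccr5 receptor antagonist",av_antivirals
"av, guanosine analog",av_antivirals
"av, hepatitis b-inhibitor",av_antivirals
"av, herpes genitalis",av_antivirals
"av, immunostimulant",av_antivirals
"av, nucleoside inhibitor",av_antivirals
"av, protease inhibitor",av_antivirals
"av, viral dna polymerase inhibitor",av_antivirals
"bm, bisphosphonate",bm_bisphosphonates
"cns, 5-ht1b/d agonist",cns_5ht1bd_agonists
"cns, 5-ht2 antagonist",cns_5ht2_antagonists
"cns, 5-ht3 antagonist",cns_5ht3_antagonists
"cns, 5ht2 antagonist",cns_5ht2_antagonists
"cns, antiepileptic, na-channel blocker",cns_antiepileptic_na_blockers
"cns, benzodiazepine",cns_benzodiazepines
"cns, benzodiazepine-like hypnotic",cns_benzodiazepines
"cns, da2 agonist",cns_da2_agonists
"cns, da2 antagonist",cns_da2_antagonists
"cns, da2-antagonist, benzamide",cns_da2_antagonists
"cns, da2-antagonist, da3 antagonist",cns_da2_antagonists
"cns, da2-antagonist/5-ht antagonist",cns_da2_antagonists
"cns, opioid, μ-agonist",cns_mu_opioid_agonists
"cns, opioid, μ-agonist, anticholinergic",cns_mu_opioid_agonists
"cns, opioid, μ-antagonist",cns_mu_opioid_antagonists
"cns, remaining, antidepressant",cns_tetracyclic_antidepressant
"cns, remaining, comt-inhibitor",cns_comt_inhibitor
"cns, remaining, α2-delta agonist",cns_alpha2delta_agonist
"cns, snri",cns_snris
"cns, ssri",cns_ssris
"cns, ssri, 5-ht antagonist",cns_ssris
"cvs, ace inhibitor",cvs_ace_inhibitors
"cvs, angiotensin ii antagonist",cvs_at2_antagonists
"cvs, anticoagulant",cvs_anticoagulants
"cvs, calcium antagonist",cvs_calcium_antagonists
"cvs, class 1c antiarrhythmic",cvs_class1c_antiarrhythmics
"cvs, endothelin antagonist",cvs_endothelin_antagonists
"cvs, imidazoline agonist",cvs_imidazoline_agonists
"cvs, loop diuretic",cvs_loop_diuretics
"cvs, na-channel block",cvs_na_channel_blockers
"cvs, pde3 inhibitor",cvs_pde3_inhibitors
"cvs, platelet aggregation inhibitor",cvs_platelet_inhibitors
"cvs, vasopressin-2 agonist",cvs_vasopressin2_agonists
"cvs, α1 agonist",cvs_alpha1_agonists
"cvs, α1 antagonist",cvs_alpha1_antagonists
"cvs, α1 antagonist and 5-ht1a",cvs_alpha1_antagonist_5ht1a
"cvs, α2 agonist",cvs_alpha2_agonists
"cvs, α2 agonist, ocular",cvs_alpha2_agonists
"cvs, β antagonist",cvs_beta_antagonists
"cvs, β antagonist/α1 blocker",cvs_beta_antagonists
"gi, 5-ht4 agonist",gi_5ht4_agonists
"gi, 5ht4 agonist",gi_5ht4_agonists
"gi, histamine h2 antagonist",gi_h2_antagonists
"gi, proton pump inhibitor",gi_ppi
"hm, dual 5-reductase inhibitor",hm_dual_5ar_inhibitors
"hm, estrogen agonist",hm_estrogen_agonists
"hm, gnrh agonist",hm_gnrh_agonists
"hm, progesterone antagonist, birth cont",hm_progestogen_combinations
"hm, progestogen–estrogen contraceptive",hm_progestogen_combinations
"hm, remaining, antiandrogen",hm_remaining
"hm, remaining, aromatase inhibitor",hm_remaining
"hm, selective estrogen modulator",hm_serm
"is, immunosuppressive",is_immunosuppressives
"is, immunosuppressive, mtor inhibitor",is_immunosuppressives
"is, immunosuppressive, s1p antagonist",is_immunosuppressives
"is, remaining",is_immunomodulators
"is, remaining, imidazothiazole derivative",is_immunomodulators
"mb, antidiabetic, dpp4 inhibitor",mb_dpp4_inhibitors
"mb, antidiabetic, α-glucosidase inhib",mb_alpha_glucosidase_inhibitors
"mb, antidiabetic, α-glucosidase inhibitor",mb_alpha_glucosidase_inhibitors
"mb, fibrate",mb_fibrates
"mb, hmg-coa reductase inhibitor",mb_statins
"rs, anticholinergic",rs_anticholinergics
"rs, corticosteroid",rs_corticosteroids
"rs, histamine h1 antagonist",rs_h1_antagonists
"rs, remaining, antifibrotic",rs_antifibrotic
"rs, remaining, leukotriene receptor antagonist",rs_leukotriene_antagonist
"rs, remaining, mast cell stabilizer",rs_mast_cell_stabilizer
"rs, remaining, methylxanthine-derivate",rs_methylxanthine
"rs, β2 agonist",rs_beta2_agonists
"ub, anticholinergic",ub_anticholinergics
"ub, anticholinergic and calcium antagonist",ub_anticholinergics
"ai, remaining*",ai_remaining
"bm, remaining*",bm_remaining
"cns, remaining*",cns_remaining
"cvs, remaining*",cvs_remaining
"gi, remaining*",gi_remaining
"mb, remaining*",mb_remaining
"ub, remaining*",ub_remaining
"zz, remaining*",zz_remaining
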