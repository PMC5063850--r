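class_id,class_name,table_of_origin,decision,n_compounds,n_with_tumors
cns_da2_agonists,"CNS, DA2 agonists",positive,TP,4,4
cns_da2_antagonists,"CNS, DA2 antagonists",positive,TP,4,3
hm_gnrh_agonists,"HM, GnRH agonists",positive,TP,4,4
hm_estrogen_agonists,"HM, estrogen agonists",positive,TP,2,2
hm_serm,"HM, selective estrogen receptor modulators",positive,TP,2,2
hm_dual_5ar_inhibitors,"HM, dual 5-reductase inhibitors",positive,TP,2,2
hm_progestogen_combinations,"HM, progestogen (combinations)",positive,TP,3,2
mb_statins,"MB, HMG-CoA reductase inhibitors",positive,TP,5,3
mb_fibrates,"MB, fibrates",positive,TP,3,2
rs_beta2_agonists,"RS, adrenergic beta2 agonists",positive,TP,5,5
rs_corticosteroids,"RS, corticosteroids",positive,TP,3,3
gi_ppi,"GI, proton pump inhibitors",positive,TP,4,3
ab_fluoroquinolones,"Antibacterial, fluoroquinolones",positive,NT,3,3
af_conazoles,Antifungal triazole derivatives,positive,NT,3,3
cvs_calcium_antagonists,"CVS, calcium antagonists",positive,TN,12,8
cvs_loop_diuretics,"CVS, loop diuretics",positive,NC,4,3
cns_5ht2_antagonists,"CNS, 5HT2 antagonists",positive,NC,2,2
gi_5ht4_agonists,"GI, 5HT4 agonists",positive,TN,3,2
ai_nsaids,"AI, NSAIDs",negative,TN,12,2
bm_bisphosphonates,"BM, bisphosphonates",negative,TN,3,0
cvs_at2_antagonists,"CVS, angiotensin II antagonists",negative,TN,5,0
cvs_class1c_antiarrhythmics,"CVS, class 1C antiarrhythmics",negative,TN,2,0
cvs_endothelin_antagonists,"CVS, endothelin antagonists",negative,TN,2,0
cvs_vasopressin2_agonists,"CVS, vasopressin-2 agonists",negative,TN,2,0
cvs_beta_antagonists,"CVS, adrenergic beta antagonists",negative,TN,13,3
cns_mu_opioid_antagonists,"CNS, mu-opioid antagonists",negative,TN,2,0
cns_ssris,"CNS, SSRIs",negative,TN,7,1
mb_dpp4_inhibitors,"MB, DPP4 inhibitors",negative,TN,4,0
is_immunosuppressives,"IS, immunosuppressives",negative,TP,6,0
rs_anticholinergics,"RS, anticholinergics",negative,TN,2,0
ai_cox2_inhibitors,"AI, COX-2 inhibitors",mixed,TN,4,2
av_antivirals,Antivirals,mixed,NT,10,4
cvs_ace_inhibitors,"CVS, ACE inhibitors",mixed,TN,9,5
cvs_alpha1_antagonists,"CVS, adrenergic alpha1 antagonists",mixed,TP,8,3
cvs_alpha1_agonists,"CVS, adrenergic alpha1 agonists",mixed,TN,2,1
cvs_alpha2_agonists,"CVS, adrenergic alpha2 agonists",mixed,TN,3,1
cvs_anticoagulants,"CVS, anticoagulants",mixed,TN,2,1
cvs_imidazoline_agonists,"CVS, imidazoline agonists",mixed,TN,2,1
cvs_na_channel_blockers,"CVS, Na-channel blockers",mixed,TN,3,1
cvs_platelet_inhibitors,"CVS, platelet aggregation inhibitors",mixed,NC,2,1
cvs_pde3_inhibitors,"CVS, PDE3 inhibitors",mixed,TN,2,1
cns_mu_opioid_agonists,"CNS, mu-opioid agonists",mixed,TN,3,1
cns_5ht1bd_agonists,"CNS, 5HT1b/d agonists",mixed,TN,4,2
cns_5ht3_antagonists,"CNS, 5HT3 antagonists",mixed,TN,2,1
cns_benzodiazepines,"CNS, benzodiazepines",mixed,TN,5,2
cns_antiepileptic_na_blockers,"CNS, antiepileptic Na-channel blockers",mixed,TN,6,2
cns_snris,"CNS, SNRIs",mixed,TN,4,2
rs_h1_antagonists,"RS, histamine H1 antagonists",mixed,TN,7,2
gi_h2_antagonists,"GI, histamine H2 antagonists",mixed,TN,4,2
mb_alpha_glucosidase_inhibitors,"MB, alpha-glycosidase inhibitors",mixed,TN,2,1
ub_anticholinergics,"UB, anticholinergics",mixed,TN,5,3
is_immunomodulators,"IS, immunomodulators",mixed,NC,2,1
ab_remaining,"Antibacterials, remaining",none,NT,1,0
af_remaining,"Antifungals, remaining",none,NT,2,1
am_remaining,"Antimicrobials, remaining",none,NT,2,0
hm_remaining,"HM, remaining (hormonal)",none,TP,2,2
cns_tetracyclic_antidepressant,"CNS, tetracyclic antidepressant",none,NC,1,1
cns_comt_inhibitor,"CNS, COMT inhibitor",none,NC,1,1
cns_alpha2delta_agonist,"CNS, alpha2-delta agonist",none,NC,1,1
cvs_alpha1_antagonist_5ht1a,"CVS, alpha1 antagonist / 5-HT1A",none,TN,1,0
rs_antifibrotic,"RS, antifibrotic",none,NC,1,1
rs_leukotriene_antagonist,"RS, leukotriene receptor antagonist",none,TN,1,0
rs_mast_cell_stabilizer,"RS, mast cell stabilizer",none,TN,1,0
rs_methylxanthine,"RS, methylxanthine derivative",none,TN,1,1
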