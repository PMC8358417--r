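"trial_id","study_name","setting","design","n","experimental_label","comparator_label","primary_endpoint","pfs_control","pfs_gain","pfs_hr","pfs_hr_lo","pfs_hr_hi","pfs_significant","os_control","os_gain","os_hr","os_hr_lo","os_hr_hi","os_significant","orr_pct","orr_significant","qol_reported","qol_global_improved","qol_subscale_improved","toxicity_reduced","toxicity_increased","early_discontinuation_reduced","subgroup_of","subgroup_prespecified","comparator_adequate","terminated_early","superseded"
"calypso","CALYPSO","platinum_sensitive","phase3_rct","976","Carboplatin/PLD","Carboplatin plus paclitaxel","NONINFERIORITY","9.4","1.9","0.82","0.72","0.94","confirmed","30.7","2.3","0.99","0.85","1.16","not_significant","","","true","false","true","false","false","true","","false","true","false","false"
"icon4","ICON4/AGO-OVAR 2.2","platinum_sensitive","phase3_rct","802","Paclitaxel plus platinum-based chemotherapy","Platinum monotherapy","OS","","","","","","","24","5","0.82","0.69","0.97","confirmed","","","false","false","false","false","false","false","","false","true","false","false"
"carbo_gem","","platinum_sensitive","phase3_rct","356","Carboplatin plus gemcitabine","Carboplatin","PFS","5.8","2.8","0.72","0.58","0.9","confirmed","17.3","0.7","0.96","0.75","1.23","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"carbo_pld_bev","","platinum_sensitive","phase3_rct","682","Carboplatin/PLD/bevacizumab","Carboplatin/gemcitabine/bevacizumab","PFS","11.7","1.7","0.81","0.68","0.91","confirmed","27.8","4.1","0.81","0.67","0.98","exploratory_or_unreported","","","false","false","false","false","false","false","","false","true","false","false"
"mito16b","MITO16b/MANGO-OV2/ENGOT-ov17","platinum_sensitive","phase3_rct","406","Carboplatin doublet plus bevacizumab","Carboplatin doublet","PFS","8.8","3","0.51","0.41","0.65","confirmed","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"icon6","ICON6","maintenance","phase3_rct","282","Cediranib","Placebo","PFS","8.7","2.3","0.56","0.44","0.72","confirmed","","","0.86","0.67","1.11","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"nova_gbrca","NOVA","maintenance","phase3_rct","203","Niraparib","Placebo","PFS","5.5","14.5","0.27","0.17","0.41","confirmed","","","","","","","","","false","false","false","false","false","false","","true","true","false","false"
"nova_non_gbrca","NOVA","maintenance","phase3_rct","350","Niraparib","Placebo","PFS","3.9","5.4","0.45","0.34","0.61","confirmed","","","","","","","","","false","false","false","false","false","false","","true","true","false","false"
"ariel3_itt","ARIEL3","maintenance","phase3_rct","564","Rucaparib","Placebo","PFS","5.4","5.4","0.36","0.3","0.45","confirmed","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"ariel3_brca","ARIEL3","maintenance","phase3_rct","196","Rucaparib","Placebo","PFS","5.4","11.2","0.23","0.16","0.34","confirmed","","","","","","","","","false","false","false","false","false","false","ariel3_itt","true","true","false","false"
"ariel3_hrd","ARIEL3","maintenance","phase3_rct","354","Rucaparib","Placebo","PFS","5.4","8.2","0.32","0.24","0.42","confirmed","","","","","","","","","false","false","false","false","false","false","ariel3_itt","true","true","false","false"
"solo2","SOLO2","maintenance","phase3_rct","295","Olaparib tablets","Placebo","PFS","5.5","13.6","0.3","0.22","0.41","confirmed","38.8","12.9","0.74","0.54","1","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"oceans","OCEANS","maintenance","phase3_rct","484","Bevacizumab plus carboplatin/gemcitabine","Carboplatin plus gemcitabine","PFS","8.4","4","0.48","0.39","0.61","confirmed","32.9","0.7","0.95","0.77","1.18","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"trabectedin_pld","","platinum_resistant","phase3_rct","672","Trabectedin plus PLD","PLD","PFS","5.8","1.5","0.79","0.65","0.96","confirmed","18.9","3.3","0.86","0.72","1.02","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"aurelia","AURELIA","platinum_resistant","phase3_rct","361","Bevacizumab plus standard chemotherapy","Standard chemotherapy","PFS","3.4","3.3","0.48","0.38","0.6","confirmed","13.3","3.3","0.85","0.66","1.08","not_significant","","","true","false","true","false","false","false","","false","true","false","false"
"trinova1","TRINOVA-1","platinum_resistant","phase3_rct","919","Trebananib plus paclitaxel","Paclitaxel","PFS","5.4","1.8","0.66","0.57","0.77","confirmed","18.3","1","0.95","0.85","1.11","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"topotecan_orr","","platinum_resistant","phase3_rct","235","Topotecan","Paclitaxel","ORR","","","","","","","","","","","","","21","confirmed","false","false","false","false","false","false","","false","true","false","false"
"study19_itt","STUDY19","maintenance","phase2_rct","265","Olaparib capsules","Placebo","PFS","4.8","3.6","0.35","0.25","0.49","confirmed","27.8","2","0.73","0.55","0.95","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"study19_brca","STUDY19","maintenance","phase2_rct","136","Olaparib capsules","Placebo","PFS","4.3","6.9","0.18","0.1","0.31","confirmed","30.2","4.7","0.62","0.42","0.93","not_significant","","","true","false","false","false","false","false","study19_itt","true","true","false","false"
"study19_wt","STUDY19","maintenance","phase2_rct","118","Olaparib capsules","Placebo","PFS","5.5","1.9","0.54","0.34","0.85","confirmed","26.6","-2.1","0.84","0.57","1.25","not_significant","","","true","false","false","false","false","false","study19_itt","true","true","false","false"
"olaparib_chemo_maint","","maintenance","phase2_rct","173","Olaparib with carboplatin/paclitaxel then olaparib maintenance","Carboplatin/paclitaxel then no further treatment","PFS","9.6","2.6","0.51","0.34","0.77","confirmed","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"trias","TRIAS","platinum_resistant","phase2_rct","185","Sorafenib plus topotecan","Topotecan plus placebo","PFS","4.4","2.3","0.6","0.43","0.83","confirmed","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"berzosertib_gem","","platinum_resistant","phase2_rct","70","Berzosertib plus gemcitabine","Gemcitabine","PFS","3.4","1.9","0.57","0.33","0.98","confirmed","9.9","3.8","0.84","0.53","1.32","not_significant","","","true","false","false","false","false","false","","false","true","false","false"
"adavosertib_gem","","platinum_resistant","phase2_rct","99","Adavosertib plus gemcitabine","Gemcitabine","PFS","3","1.6","0.55","0.35","0.9","confirmed","7.2","4.2","0.56","0.35","0.91","confirmed","","","false","false","false","false","false","false","","false","true","false","false"
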