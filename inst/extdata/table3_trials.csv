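"trial_id","study_name","setting","design","n","experimental_label","comparator_label","primary_endpoint","pfs_control","pfs_gain","pfs_hr","pfs_hr_lo","pfs_hr_hi","pfs_significant","os_control","os_gain","os_hr","os_hr_lo","os_hr_hi","os_significant","orr_pct","orr_significant","qol_reported","qol_global_improved","qol_subscale_improved","toxicity_reduced","toxicity_increased","early_discontinuation_reduced","subgroup_of","subgroup_prespecified","comparator_adequate","terminated_early","superseded"
"farletuzumab","","platinum_sensitive","phase3_rct","1100","Farletuzumab with carboplatin/taxane","Placebo with carboplatin/taxane","PFS","9","0.7","0.99","0.81","1.21","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"carbo_topotecan","","platinum_sensitive","phase3_rct","550","Carboplatin/topotecan","Carboplatin plus physician choice chemotherapy","PFS","10","0","","","","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"mito8","MITO-8","platinum_sensitive","phase3_rct","215","Non-platinum-based chemotherapy","Platinum-based chemotherapy","OS","9","-4","","","","not_significant","24.5","-2.7","","","","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"micellar","","platinum_sensitive","phase3_rct","789","Carboplatin/paclitaxel micellar","Carboplatin plus paclitaxel","NONINFERIORITY","10.1","0.2","0.86","0.72","1.03","not_significant","","","","","","","","","true","false","false","false","true","false","","false","true","false","false"
"vismodegib","","maintenance","phase2_rct","104","Vismodegib","Placebo","PFS","5.8","1.7","0.79","0.46","1.35","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"gog0213","GOG-0213","maintenance","phase3_rct","674","Carboplatin/paclitaxel plus bevacizumab","Carboplatin/paclitaxel plus placebo","OS","","","","","","","37.3","4.9","0.83","0.68","1.01","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"pld_vs_topotecan","","platinum_resistant","phase3_rct","474","PLD","Topotecan","PFS","3.9","-0.2","","","","not_significant","13.8","0.69","0.82","0.68","1","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"epidox_paclitaxel","","platinum_resistant","phase3_rct","234","Epidoxorubicin plus paclitaxel","Paclitaxel","OS","","","","","","","14","-2","","","","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"pld_vs_gemcitabine","","platinum_resistant","phase3_rct","195","PLD","Gemcitabine","PFS","3.1","0.5","","","","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"pld_ttp","","platinum_resistant","phase3_rct","153","PLD","Gemcitabine","PFS","3.7","0.9","","","","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"topo_etoposide_gem","","platinum_resistant","phase3_rct","502","Topotecan/etoposide or topotecan/gemcitabine","Topotecan","OS","","","","","","","17.2","0.6","1.18","0.9","1.53","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"canfosfamide","","platinum_resistant","phase3_rct","461","Canfosfamide","PLD or topotecan","OS","","","","","","","13.5","-5","","","","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"pertuzumab_gem","","platinum_resistant","phase2_rct","130","Pertuzumab plus gemcitabine","Gemcitabine plus placebo","PFS","2.9","0","0.66","0.43","1.03","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"pertuzumab_carbo","","platinum_resistant","phase2_rct","149","Pertuzumab plus carboplatin doublet","Carboplatin doublet","PFS","8.6","-0.7","1.16","0.9","1.49","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"pac_carbo_or_topo","","platinum_resistant","phase2_rct","165","Paclitaxel/carboplatin or paclitaxel/topotecan","Paclitaxel","PFS","3.7","1.1","","","","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"olaparib_dose","","platinum_resistant","phase2_rct","97","Olaparib 200 mg or 400 mg","PLD","PFS","7.1","","0.88","0.62","1.28","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"patupilone","","platinum_resistant","phase3_rct","829","Patupilone","PLD","OS","","","","","","","12.7","0.5","0.93","0.79","1.09","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"docetaxel_vandetanib","","platinum_resistant","phase2_rct","129","Docetaxel plus vandetanib","Docetaxel","PFS","3.5","-0.5","1.01","0.79","1.27","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"seribantumab_pac","","platinum_resistant","phase2_rct","223","Seribantumab plus paclitaxel","Paclitaxel","PFS","3.7","0.1","1.03","0.74","1.43","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"motolimod_pld","","platinum_resistant","phase2_rct","297","Motolimod plus PLD","PLD","PFS","5.2","-0.4","","","","not_significant","18.9","-0.8","","","","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"reovirus_pac","","platinum_resistant","phase2_rct","108","Oncolytic reovirus plus paclitaxel","Paclitaxel","PFS","4.3","0.1","1.11","0.78","1.59","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"pazopanib_pac","","platinum_resistant","phase2_rct","106","Pazopanib plus paclitaxel","Paclitaxel","PFS","6.2","1.3","0.84","0.57","1.22","not_significant","23.3","-2.6","1.04","0.6","1.79","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"cabozantinib_pac","","platinum_resistant","phase2_rct","174","Cabozantinib plus paclitaxel","Paclitaxel","PFS","5.5","-0.2","1.11","0.77","1.61","not_significant","","","2.27","1.17","2.63","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"olaratumab_pld","","platinum_resistant","phase2_rct","123","Olaratumab plus PLD","PLD","PFS","4","0.2","1.04","0.7","1.56","not_significant","16.2","0.4","1.1","0.7","1.71","not_significant","","","false","false","false","false","false","false","","false","true","false","false"
"linsitinib_pac","","platinum_resistant","phase2_rct","152","Linsitinib plus paclitaxel","Paclitaxel","PFS","5.6","-1.4","1.2","0.75","1.91","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"alisertib_pac","","platinum_resistant","phase2_rct","191","Alisertib plus paclitaxel","Paclitaxel","PFS","4.7","2","0.75","0.58","0.96","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
"guadecitabine_carbo","","platinum_resistant","phase2_rct","100","Carboplatin plus guadecitabine","Physician choice chemotherapy","PFS","2.1","1.6","0.69","0.46","1","not_significant","","","","","","","","","false","false","false","false","false","false","","false","true","false","false"
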