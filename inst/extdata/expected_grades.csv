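trial_id,form,preliminary,adjustment,final,provenance
calypso,2c,3,0,3,"Phase III table, CALYPSO row: 3 (2c), global QoL equal but better subscales"
icon4,2a,4,0,4,"Phase III table, ICON4/AGO-OVAR 2.2 row: 4 (2a)"
carbo_gem,2b,3,-1,2,"Phase III table, carboplatin plus gemcitabine row: 2 (2b), -1 no QoL and no OS benefit"
carbo_pld_bev,2b,1,0,1,"Phase III table, carboplatin/PLD/bevacizumab row: 1 (2b), OS exploratory"
mito16b,2b,3,0,3,"Phase III table, MITO16b row: 3 (2b)"
icon6,2b,2,-1,1,"Phase III table, cediranib ICON6 ITT row: 1 (2b), -1 no QoL and no OS benefit"
nova_gbrca,2b,3,0,3,"Phase III table, niraparib gBRCA cohort: 3 (2b)"
nova_non_gbrca,2b,3,0,3,"Phase III table, niraparib non-gBRCA cohort: 3 (2b)"
ariel3_itt,2b,3,0,3,"Phase III table, rucaparib ARIEL3 ITT row: 3 (2b)"
ariel3_brca,2b,3,0,3,"Phase III table, rucaparib ARIEL3 BRCA-mutated subgroup: 3 (2b)"
ariel3_hrd,2b,3,0,3,"Phase III table, rucaparib ARIEL3 HRD subgroup: 3 (2b)"
solo2,2b,3,-1,2,"Phase III table, olaparib tablets SOLO2 ITT row: 2 (2b), -1 for no OS benefit"
oceans,2b,3,-1,2,"Phase III table, bevacizumab OCEANS row: 2 (2b), -1 no QoL and no OS benefit"
trabectedin_pld,2b,3,-1,2,"Phase III table, trabectedin plus PLD row: 2 (2b); CI lower 0.65 and gain 1.5 sit exactly on the grade-3 band bounds"
aurelia,2b,3,1,4,"Phase III table, AURELIA row: 4 (2b), +1 QoL benefit (prespecified GI-subscale improvement)"
trinova1,2b,3,-1,2,"Phase III table, trebananib TRINOVA-1 row: 2 (2b); OS gain printed in a digit run, read as 1.0 month (typographically ambiguous)"
topotecan_orr,3,2,0,2,"Phase III table, topotecan vs paclitaxel row: 2 (3), ORR 21%"
study19_itt,2b,3,-1,2,"Phase II table, olaparib capsules STUDY19 ITT row: 2 (2b), OS P-value did not meet prespecified criterion"
study19_brca,2b,3,-1,2,"Phase II table, STUDY19 BRCA-mutated subgroup: 2 (2b)"
study19_wt,2b,3,-1,2,"Phase II table, STUDY19 BRCA wild-type subgroup: 2 (2b)"
olaparib_chemo_maint,2b,2,0,2,"Phase II table, olaparib during carboplatin/paclitaxel then maintenance: 2 (2b)"
trias,2b,3,0,3,"Phase II table, sorafenib plus topotecan TRIAS row: 3 (2b)"
berzosertib_gem,2b,3,-1,2,"Phase II table, berzosertib plus gemcitabine row: 2 (2b), -1 no QoL and no OS benefit"
adavosertib_gem,2a,4,0,4,"Phase II table, adavosertib plus gemcitabine row: 4 (2a), confirmed secondary OS benefit"
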