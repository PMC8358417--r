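label,class
carboplatin/paclitaxel,platinum_based
platinum monotherapy,platinum_based
carboplatin,platinum_based
carboplatin/gemcitabine,platinum_based
carboplatin/gemcitabine/bevacizumab,platinum_based
carboplatin doublet,platinum_based
carboplatin/physician choice chemotherapy,platinum_based
carboplatin/taxane,platinum_based
placebo with carboplatin/taxane,platinum_based
platinum-based chemotherapy,platinum_based
carboplatin/paclitaxel/placebo,platinum_based
non-platinum-based chemotherapy,other
placebo,placebo_or_no_treatment
carboplatin/paclitaxel then no further treatment,placebo_or_no_treatment
pld,guideline_listed
topotecan,guideline_listed
paclitaxel,guideline_listed
gemcitabine,guideline_listed
gemcitabine/placebo,guideline_listed
docetaxel,guideline_listed
standard chemotherapy,guideline_listed
physician choice chemotherapy,guideline_listed
pld or topotecan,guideline_listed
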