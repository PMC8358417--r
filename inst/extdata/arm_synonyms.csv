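variant,canonical
pegylated liposomal doxorubicin,pld
liposomal doxorubicin,pld
carboplatin/pegylated liposomal doxorubicin,carboplatin/pld
platinum monotherapy (carboplatin or cisplatin),platinum monotherapy
carboplatin or cisplatin monotherapy,platinum monotherapy
topotecan/placebo,topotecan
chemotherapy,standard chemotherapy
standard chemotherapy (either pld or paclitaxel or topotecan),standard chemotherapy
physician choice pld or topotecan or paclitaxel or gemcitabine,physician choice chemotherapy
paclitaxel/platinum-based chemotherapy,paclitaxel/platinum
paclitaxel/platinum,paclitaxel/platinum
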