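group,neutrophils,neutrophils_se,lymphocytes,lymphocytes_se,monocytes,monocytes_se,eosinophils,eosinophils_se,basophils,basophils_se
HC,56.4,7.8,29.6,5.5,4.5,0.7,2.1,0.6,5.6,5.5
pre,57.9,4.5,29.5,4.4,7.4,0.7,4.7,0.8,0.5,0.1
post,65.0,2.6,25.6,2.6,5.7,0.8,3.3,0.7,0.4,0.1
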