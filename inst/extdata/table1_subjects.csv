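subject,group,age,sex,allergen,pc20_pre,pc20_post
A1,asthmatic,28,F,Cat Pelt,12.8,ND
A2,asthmatic,34,F,Cat Pelt,2.7,6.1
A3,asthmatic,27,M,Cat Pelt,4.5,1.8
A4,asthmatic,42,F,Cat Hair,5.3,8.6
A5,asthmatic,23,F,Cat Hair,0.3,0.2
A6,asthmatic,26,F,Cat Hair,5.1,1.5
A7,asthmatic,49,F,Cat Hair,3.6,1
HC1,HC,33,F,ND,,
HC2,HC,43,F,ND,,
HC3,HC,21,M,ND,,
HC4,HC,43,M,ND,,
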