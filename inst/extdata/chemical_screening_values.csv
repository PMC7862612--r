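chemical,abbrev,ic10_uM,ec20_uM,ec20_censored,max_tested_uM
dexamethasone,Dex,1515,400,FALSE,10
diclofenac,DCF,5044,463,FALSE,50
benzo(a)pyrene,BaP,20,NA,TRUE,2
bisphenol A,BPA,68,25,FALSE,5
ethinylestradiol,EE2,60,31,FALSE,5
ethylene glycol,EG,977000,1000000,FALSE,75000
butanol,But,26000,100000,FALSE,10000
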