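"region","sex","rural","urban","urbanization","pct_rural","pct_urban","pct_urbanization","exact"
"Central Asia, Middle East and north Africa","men",1.3,1.33,0.09,48,49,3,TRUE
"Central Asia, Middle East and north Africa","women",1.96,1.31,0.06,59,39,2,TRUE
"East and southeast Asia","men",1.99,0.66,0.33,67,22,11,TRUE
"East and southeast Asia","women",1.81,0.47,0.18,73,19,7,FALSE
"Latin America and the Caribbean","men",0.86,1.73,0.17,31,63,6,TRUE
"Latin America and the Caribbean","women",1.29,2.01,0.06,38,60,2,TRUE
"Oceania","men",2.24,0.24,0,90,10,0,TRUE
"Oceania","women",2.41,0.53,0,81,19,0,FALSE
"South Asia","men",1.99,0.2,0.12,86,8,5,FALSE
"South Asia","women",2.18,0.36,0.19,80,13,7,TRUE
"Sub-Saharan Africa","men",1.14,0.39,0.23,64,22,14,FALSE
"Sub-Saharan Africa","women",1.37,0.58,0.45,57,24,19,TRUE
"Central and eastern Europe","men",0.59,1.1,0,35,65,0,TRUE
"Central and eastern Europe","women",0.14,0.13,-0.02,NA,NA,NA,NA
"High-income Asia Pacific","men",0.48,1.15,-0.04,31,72,-2,FALSE
"High-income Asia Pacific","women",0.12,-0.02,-0.1,NA,NA,NA,NA
"High-income western countries","men",0.58,1.8,-0.01,24,76,0,TRUE
"High-income western countries","women",0.39,1.44,0,21,79,0,TRUE
"World","men",1.24,0.65,0.3,57,30,14,TRUE
"World","women",1.22,0.56,0.25,60,28,13,FALSE
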