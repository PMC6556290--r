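kind,label,age_lo,age_hi,n_eff,value,source
incidence,ESCC,30,34,1e+05,3.4,registry
incidence,ESCC,35,39,1e+05,12.4,registry
incidence,ESCC,40,44,1e+05,42.4,registry
incidence,ESCC,45,49,1e+05,93.1,registry
incidence,ESCC,50,54,1e+05,238.7,registry
incidence,ESCC,55,59,1e+05,475.8,registry
incidence,ESCC,60,64,1e+05,519.6,registry
incidence,ESCC,65,69,1e+05,636.8,registry
incidence,ESCC,70,74,1e+05,878.9,registry
incidence,ESCC,75,79,1e+05,925.1,registry
incidence,ESCC,80,84,1e+05,1145.1,registry
incidence,ESCC,85,89,1e+05,967.6,registry
prevalence,BCH_MD,40,44,1000,13.1,survey
prevalence,BCH_MD,45,49,1000,16.7,survey
prevalence,BCH_MD,50,54,1000,21.1,survey
prevalence,BCH_MD,55,59,1000,22.6,survey
prevalence,BCH_MD,60,64,1000,25.8,survey
prevalence,BCH_MD,65,69,1000,24.3,survey
prevalence,MD,40,44,1000,1.24,survey
prevalence,MD,45,49,1000,2.26,survey
prevalence,MD,50,54,1000,3.62,survey
prevalence,MD,55,59,1000,5.37,survey
prevalence,MD,60,64,1000,5.5,survey
prevalence,MD,65,69,1000,5.67,survey
prevalence,SD,40,44,1000,0.34,survey
prevalence,SD,45,49,1000,0.77,survey
prevalence,SD,50,54,1000,1.71,survey
prevalence,SD,55,59,1000,2.58,survey
prevalence,SD,60,64,1000,2.64,survey
prevalence,SD,65,69,1000,3.84,survey
stage_proportion,I,15,99,1000,0.15,synthetic_placeholder
stage_proportion,II,15,99,1000,0.35,synthetic_placeholder
stage_proportion,III,15,99,1000,0.3,synthetic_placeholder
stage_proportion,IV,15,99,1000,0.2,synthetic_placeholder
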