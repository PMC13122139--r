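"feature","category"
"age","sociodemographic-geographic"
"female","sociodemographic-geographic"
"rural","sociodemographic-geographic"
"income_q1","sociodemographic-geographic"
"ethnic_q5","sociodemographic-geographic"
"dependency_q5","sociodemographic-geographic"
"instability_q5","sociodemographic-geographic"
"deprivation_q5","sociodemographic-geographic"
"region_central","sociodemographic-geographic"
"region_metropolitan","sociodemographic-geographic"
"region_southwestern","sociodemographic-geographic"
"region_northern","sociodemographic-geographic"
"care_support_hist","mobility-disability"
"fall_hist","mobility-disability"
"fracture_hist","mobility-disability"
"rehab_hist","mobility-disability"
"mobility","mobility-disability"
"dementia","multimorbidity-health"
"comorbidity","multimorbidity-health"
"palliative_hist","multimorbidity-health"
"noise_hist","multimorbidity-health"
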