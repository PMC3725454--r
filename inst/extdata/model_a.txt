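# Four-factor AUD severity model.
# Severity is endogenous: marker loading on ADS fixed to 1, disturbance free.
# The three predictor factors are exogenous with variances fixed to 1 and
# all loadings free; their covariances are free.
Severity =~ 1*ADS + PACS + COUNT + DRINC + CIWA
AlcoholUse =~ DPDD + BINGE_PCT
Affective =~ BAI + BDI
Motivation =~ STEPS + RECOG + AMBIV
Severity ~ AlcoholUse + Affective + Motivation
AlcoholUse ~~ 1*AlcoholUse
Affective ~~ 1*Affective
Motivation ~~ 1*Motivation
AlcoholUse ~~ Affective
AlcoholUse ~~ Motivation
Affective ~~ Motivation
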