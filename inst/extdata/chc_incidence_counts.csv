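chc,incident,at_risk
abnormal_glucose_metabolism,302,1680
cardiomyopathy,168,1742
hypercholesterolemia,479,1461
hypertriglyceridemia,399,1539
hypertension,727,1365
myocardial_infarction,47,1892
obesity,942,1519
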