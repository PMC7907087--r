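name,log_kow,log_hlc,mw,melting_point_c,water_solubility
difenoconazole,4.3,-11.05,,,
"2,4-di-tert-butylphenol",5.19,-5.43,,,
naphthalene,3.3,-3.36,,,
propiconazole,3.72,,,,
"3,4-dichloroaniline",2.69,-5.98,,,
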