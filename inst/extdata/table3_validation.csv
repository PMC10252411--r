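variable,max,min,median,q1,q3,average
alcohol,19.03,5.67,7.68,6.79,8.18,7.98
ph,3.99,3.27,3.63,3.54,3.68,3.61
malic_acid,1.45,0.00,0.48,0.37,0.61,0.50
titratable_acidity,1.62,0.33,0.55,0.48,0.69,0.61
residual_sugar,17059.00,1.00,691.17,11.67,1953.25,1758.83
polyphenols,5356.2,62.0,409.4,258.0,744.4,793.8
hydroxybenzoic,94.3,16.0,24.0,20.0,31.3,31.4
hydroxycinnamic,390.3,15.0,75.7,30.3,126.3,101.5
abs320,0.4266,0.0248,0.0812,0.0558,0.1730,0.1313
abs280,3.2950,0.0476,0.2130,0.1028,0.3730,0.4811
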