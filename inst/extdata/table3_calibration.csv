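variable,max,min,median,q1,q3,average
alcohol,20.22,5.03,7.28,6.69,8.16,7.73
ph,3.98,3.26,3.62,3.50,3.82,3.64
malic_acid,0.83,0.00,0.47,0.22,0.61,0.40
titratable_acidity,0.93,0.25,0.56,0.43,0.69,0.56
residual_sugar,7689.00,1.00,361.83,8.08,1738.67,1248.51
polyphenols,5399.0,50.4,435.7,210.5,702.1,824.1
hydroxybenzoic,109.7,15.0,24.5,20.8,28.8,28.9
hydroxycinnamic,398.0,7.0,76.5,27.0,139.3,101.2
abs320,0.3758,0.0120,0.0760,0.0523,0.1492,0.1117
abs280,4.5855,0.0279,0.2329,0.1207,0.3858,0.5940
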