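name,persistency_days,aeq,ld50_ug_per_bee,likely_exposure,mrl_mg_per_kg,dose_ml_per_ha
Abamectin,28,0.002,0.03,3,0.02,750
Dodine,20,3.267,145,3,5,2242
Dimethoate,7,0.0081,0.12,3,0.05,750
Clofentezine,40,6.06,48,3,0.05,400
Iprodione,14,17.28,400,3,10,1169
DDT,2000,0.198,8.8,3,0.2,2242
Fenthion,34,1.11,0.22,3,2,10
Acephate,3,0.117,1.8,3,1,780
Chlorpyrifos,30,0.00214,0.072,3,0.05,1700
Methidathion,7,0.025,0.27,3,0.5,535.117
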