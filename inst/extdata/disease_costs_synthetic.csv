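country,disease,mix_share,unit_cost
India,copd,0.25,1000
India,stroke,0.20,2000
India,heart_disease,0.25,2500
India,cancers,0.30,4000
Indonesia,copd,0.25,1900
Indonesia,stroke,0.20,3800
Indonesia,heart_disease,0.25,4750
Indonesia,cancers,0.30,7600
Bangladesh,copd,0.25,620
Bangladesh,stroke,0.20,1240
Bangladesh,heart_disease,0.25,1550
Bangladesh,cancers,0.30,2480
Philippines,copd,0.25,1400
Philippines,stroke,0.20,2800
Philippines,heart_disease,0.25,3500
Philippines,cancers,0.30,5600
Vietnam,copd,0.25,1100
Vietnam,stroke,0.20,2200
Vietnam,heart_disease,0.25,2750
Vietnam,cancers,0.30,4400
Armenia,copd,0.25,1600
Armenia,stroke,0.20,3200
Armenia,heart_disease,0.25,4000
Armenia,cancers,0.30,6400
China,copd,0.25,2600
China,stroke,0.20,5200
China,heart_disease,0.25,6500
China,cancers,0.30,10400
Mexico,copd,0.25,3400
Mexico,stroke,0.20,6800
Mexico,heart_disease,0.25,8500
Mexico,cancers,0.30,13600
Turkey,copd,0.25,4600
Turkey,stroke,0.20,9200
Turkey,heart_disease,0.25,11500
Turkey,cancers,0.30,18400
Brazil,copd,0.25,2900
Brazil,stroke,0.20,5800
Brazil,heart_disease,0.25,7250
Brazil,cancers,0.30,11600
Colombia,copd,0.25,2500
Colombia,stroke,0.20,5000
Colombia,heart_disease,0.25,6250
Colombia,cancers,0.30,10000
Thailand,copd,0.25,3000
Thailand,stroke,0.20,6000
Thailand,heart_disease,0.25,7500
Thailand,cancers,0.30,12000
Chile,copd,0.25,4200
Chile,stroke,0.20,8400
Chile,heart_disease,0.25,10500
Chile,cancers,0.30,16800
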