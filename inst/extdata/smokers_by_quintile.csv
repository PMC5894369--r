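country,quintile,smokers_m
India,1,7.3
India,2,10.2
India,3,9.5
India,4,9.1
India,5,10.0
Indonesia,1,13.6
Indonesia,2,12.0
Indonesia,3,9.8
Indonesia,4,9.7
Indonesia,5,7.7
Bangladesh,1,3.0
Bangladesh,2,3.3
Bangladesh,3,3.1
Bangladesh,4,3.8
Bangladesh,5,3.0
Philippines,1,3.0
Philippines,2,2.8
Philippines,3,2.6
Philippines,4,2.5
Philippines,5,2.2
Vietnam,1,3.7
Vietnam,2,3.3
Vietnam,3,2.6
Vietnam,4,2.6
Vietnam,5,2.4
Armenia,1,0.1
Armenia,2,0.1
Armenia,3,0.1
Armenia,4,0.1
Armenia,5,0.1
China,1,63.9
China,2,68.5
China,3,63.1
China,4,47.7
China,5,47.7
Mexico,1,1.6
Mexico,2,2.0
Mexico,3,1.8
Mexico,4,2.0
Mexico,5,2.1
Turkey,1,1.8
Turkey,2,2.4
Turkey,3,2.9
Turkey,4,2.6
Turkey,5,1.9
Brazil,1,4.2
Brazil,2,3.6
Brazil,3,2.9
Brazil,4,3.1
Brazil,5,2.0
Colombia,1,0.6
Colombia,2,0.6
Colombia,3,0.7
Colombia,4,0.6
Colombia,5,0.6
Thailand,1,2.8
Thailand,2,3.3
Thailand,3,2.7
Thailand,4,2.3
Thailand,5,1.0
Chile,1,0.5
Chile,2,0.6
Chile,3,0.7
Chile,4,0.7
Chile,5,0.8
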