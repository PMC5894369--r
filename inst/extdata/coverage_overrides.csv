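country,quintile,disease,coverage_fraction,public_cost_share
Mexico,1,copd,1.00,1.00
Mexico,1,stroke,0.00,0.00
Mexico,1,heart_disease,0.00,0.00
Mexico,1,cancers,0.00,0.00
Mexico,2,copd,1.00,1.00
Mexico,2,stroke,0.00,0.00
Mexico,2,heart_disease,0.00,0.00
Mexico,2,cancers,0.00,0.00
Mexico,3,copd,0.82,0.70
Mexico,3,stroke,0.82,0.70
Mexico,3,heart_disease,0.82,0.70
Mexico,3,cancers,0.82,0.70
Mexico,4,copd,0.82,0.70
Mexico,4,stroke,0.82,0.70
Mexico,4,heart_disease,0.82,0.70
Mexico,4,cancers,0.82,0.70
Mexico,5,copd,0.82,0.70
Mexico,5,stroke,0.82,0.70
Mexico,5,heart_disease,0.82,0.70
Mexico,5,cancers,0.82,0.70
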