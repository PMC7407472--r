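condition,mutation_rate,ci_low,ci_high,iptg_uM,atc_ng_ml
High,2.2e-7,1.6e-7,2.9e-7,0,0
HiMid,4.1e-8,2.6e-8,5.9e-8,50,0
Mid,1.4e-8,0.64e-8,2.5e-8,2000,0
LoMid,3.8e-9,1.2e-9,7.4e-9,2000,2
Low,1.7e-9,0.41e-9,3.6e-9,2000,10
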