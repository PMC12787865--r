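food_class,volume,weight
rice,400000,221.6
rice,560000,286.5
rice,720000,400.1
rice,880000,487.7
rice,1040000,552.1
rice,1200000,577.8
chicken,300000,258.8
chicken,420000,377.2
chicken,540000,460.9
chicken,660000,636.2
chicken,780000,705.7
chicken,900000,768.8
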