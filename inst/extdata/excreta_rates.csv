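stock_class,age_class,region,urine_n_kg_head,dung_n_kg_head
dairy_milking,adult,default,8.2,2.9
dairy_heifer,young,default,4.1,1.6
beef_cattle,adult,default,5.5,2.2
beef_cattle,young,default,3.2,1.3
sheep_ewe,adult,default,0.95,0.35
sheep_lamb,young,default,0.45,0.2
deer_hind,adult,default,1.8,0.7
pig,all,default,1.1,0.6
poultry,all,default,0.05,0.04
goat,all,default,0.8,0.35
horse,all,default,3.0,1.4
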