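crop_id,yield_t_ha,residue_fraction,n_conc_ag,n_conc_bg,cn_ratio,rooting
wheat,9,0.35,5.5,1.8,80,intermediate
barley,8,0.35,5.0,1.7,75,intermediate
oats,7,0.35,5.2,1.7,70,intermediate
maize,12,0.4,6.0,2.0,60,deep
onions,45,0.2,2.4,0.8,15,shallow
potatoes,50,0.15,3.0,1.0,20,shallow
brassicas,60,0.25,3.5,1.2,14,shallow
squash,35,0.3,2.8,0.9,16,shallow
peas,6,0.5,12,4,18,intermediate
lucerne,14,0.3,8,3,13,deep
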