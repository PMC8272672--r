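category,acute_pos,acute_n,chronic_pos,chronic_n
meniscus_tear,30,43,12,17
medial_collateral_ligament,20,43,7,17
lateral_collateral_ligament,13,43,5,17
cartilage_injury,15,43,7,17
bone_contusion,10,43,3,17
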