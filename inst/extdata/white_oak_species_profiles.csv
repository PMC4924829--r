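continent,species,n_individuals,n_individuals_trnDT,psaI-ycf4,psbE-petL,trnLF,trnCD,trnDT
Europe,Q. robur,531,103,178,185,135,123,86/101
Europe,Q. petraea,273,12,178,185,135,123,86/101
Europe,Q. pubescens,158,0,178,185,135,123,
NorthAmerica,Q. alba,15,4,178,185,130,115,88/101
NorthAmerica,Q. macrocarpa,12,7,178,185,130,115,88/101
NorthAmerica,Q. bicolor,7,4,178,185,130,115,88/101
NorthAmerica,Q. garryana,4,0,178,185,130,115,
NorthAmerica,Q. lyrata,4,2,178,185,130,115,88/101
NorthAmerica,Q. michauxii,5,1,178,185,130,115,88/101
NorthAmerica,Q. stellata,8,1,178,185,130,115,88/101
NorthAmerica,Q. prinoides,6,0,178,185,130,115,
Asia,Q. mongolica,316,420,174,179,135,123,86/71
Asia,Q. dentata,9,5,174,179,135,123,86/71
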