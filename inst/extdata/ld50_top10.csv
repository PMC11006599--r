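compound_id,pesticide_type,chemical_group,route,time_h,ld50_ug_per_bee,qualifier,loq_ug_per_kg
indoxacarb,insecticide,Oxadiazine,oral,24,0.1560,exact,5.0
spinosad,insecticide,Spinosyn,oral,24,0.0303,exact,5.0
chlorpyrifos-ethyl,insecticide,Organophosphate,oral,24,0.1090,exact,5.0
deltamethrin,insecticide,Pyrethroid,oral,24,0.0358,exact,5.0
dimethoate,insecticide,Organophosphate,oral,24,0.1000,exact,1.0
imidacloprid,insecticide,Neonicotinoid,oral,24,0.0424,exact,1.0
cyfluthrin,insecticide,Pyrethroid,oral,24,0.0255,exact,1.0
dithianon,fungicide,Quinone,oral,24,62.700,greater_than,50.0
etofenprox,insecticide,Pyrethroid,oral,24,0.2020,exact,5.0
chlorpyrifos-methyl,insecticide,Organophosphate,oral,24,0.1620,exact,5.0
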