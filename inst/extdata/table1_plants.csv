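plant,species,restricted_distribution,archaeobotany_present,archaeobotany_context_uses,medieval_uses,linguistic_uses,linguistic_old_norse,ethnobotany_uses
yarrow,Achillea millefolium,0,1,,Med;SSR,Food;IndCraft;Med,1,Food;IndCraft;Med;SSR;Vet
angelica,Angelica archangelica,0,1,,Agri;IndCraft;SSR,Food;IndCraft,1,AnFood;Food;IndCraft;Med;SSR;Vet
bunchberry,Cornus suecica,0,1,Food,,AnFood;Med,1,AnFood;Food;Med;SSR
spindle,Euonymus europaeus,1,1,IndCraft,present,IndCraft;Med,0,Constr;Fuel;IndCraft;Med;SSR;Vet
meadowsweet,Filipendula ulmaria,0,1,AnFood,Agri;Med,Food,0,Agri;AnFood;Food;IndCraft;Med;SSR;Vet
hops,Humulus lupulus,1,1,Food;IndCraft,Agri;Food;Med,,1,Agri;AnFood;Food;Fuel;IndCraft;Med;SSR;Vet
woad,Isatis tinctoria,1,1,IndCraft,Med,IndCraft,0,IndCraft
juniper,Juniperus communis,0,1,Constr,Agri;Fuel;Med,Fuel;IndCraft,1,Agri;AnFood;Constr;Food;Fuel;IndCraft;Med;SSR;Vet
field_scabious,Knautia arvensis,0,1,,,Food;Med,0,Agri;IndCraft;Med;SSR
roseroot,Rhodiola rosea,0,0,,,Med,1,AnFood;Food;IndCraft;Med;SSR;Vet
sorrel,Rumex acetosa,0,1,,Food;Med;SSR,Food,1,AnFood;Food;IndCraft;Med;SSR;Vet
chickweed,Stellaria media,0,1,,Med,Agri;AnFood;Food;IndCraft;Med,1,AnFood;Food;IndCraft;Med
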