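((((Ptychoramphus_aleuticus,(Aethia_pusilla,(Aethia_cristatella,Cyclorrhynchus_psittacula))),(Cerorhinca_monocerata,(Fratercula_corniculata,(Fratercula_arctica,Fratercula_cirrhata)))),((Alle_alle,(Alca_torda,(Uria_aalge,Uria_lomvia))),((Synthliboramphus_wumizusume,(Synthliboramphus_antiquus,Synthliboramphus_hypoleucus)),((Cepphus_carbo,(Cepphus_columba,Cepphus_grylle)),Brachyramphus_marmoratus)))),((Aptenodytes_forsteri,Aptenodytes_patagonicus),((Pygoscelis_adeliae,(Pygoscelis_antarctica,Pygoscelis_papua)),(((Spheniscus_demersus,(Spheniscus_humboldti,Spheniscus_magellanicus)),Eudyptula_minor),(Megadyptes_antipodes,((Eudyptes_chrysocome,Eudyptes_chrysolophus),(Eudyptes_pachyrhynchus,Eudyptes_sclateri)))))));
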