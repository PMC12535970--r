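level,class,train,validation,test,test_other
lineage,Avena,180,59,55,0
lineage,Hordeum,129,42,40,0
lineage,Secale,187,60,59,0
lineage,Triticum,204,66,65,287
lineage,Poeae confusers,58,19,17,0
lineage,Triticodae confusers,196,64,63,0
species,Aegilops biuncialis,9,4,8,0
species,Aegilops cylindrica,14,3,3,0
species,Aegilops geniculata,13,5,2,0
species,Aegilops neglecta,17,1,2,0
species,Aegilops speltoides,9,5,6,20
species,Aegilops tauschii,13,6,1,20
species,Avena barbata,16,5,2,22
species,Avena fatua,15,8,1,40
species,Avena nuda,13,5,2,0
species,Avena sativa,11,4,5,41
species,Avena sterilis,9,7,7,20
species,Avena strigosa,15,4,1,20
species,Avena wiestii,13,4,4,0
species,Bromus erectus,13,3,5,0
species,Bromus ramosus,12,3,7,0
species,Dasypyrum villosum,13,3,4,0
species,Elymus caninus,15,1,4,0
species,Elymus repens,12,3,5,0
species,Helictochloa pratensis,11,4,5,0
species,Helictotrichon sedenense,12,6,3,0
species,Hordelymus europaeus,16,3,1,0
species,Hordeum marinum,10,5,5,0
species,Hordeum murinum,10,6,4,20
species,Hordeum secalinum,12,6,2,0
species,Hordeum vulgare,10,6,5,110
species,Parapholis incurva,11,4,5,0
species,Secale africanum,10,5,5,0
species,Secale anatolicum,13,6,3,20
species,Secale cereale,12,6,3,105
species,Secale segetale,10,8,2,0
species,Secale strictum,12,3,5,0
species,Secale sylvestre,10,4,6,20
species,Secale vavilovii,7,4,10,17
species,Thinopyrum junceum,14,5,2,0
species,Triticum aestivum,12,5,5,208
species,Triticum monococcum,13,4,3,61
species,Triticum timopheevii,15,1,4,20
species,Triticum turgidum,14,5,5,207
species,Triticum urartu,11,5,4,20
subspecies,Triticum aestivum ssp. compactum,9,5,7,0
subspecies,Triticum aestivum ssp. macha,14,1,5,0
subspecies,Triticum aestivum ssp. spelta,10,7,5,20
subspecies,Triticum aestivum ssp. sphaerococcum,12,5,3,23
subspecies,Triticum monococcum ssp. aegilopoides,14,5,1,20
subspecies,Triticum monococcum ssp. monococcum,12,5,3,21
subspecies,Triticum timopheevii ssp. timopheevii,12,2,6,20
subspecies,Triticum turgidum ssp. carthlicum,13,4,3,0
subspecies,Triticum turgidum ssp. dicoccoides,14,5,5,25
subspecies,Triticum turgidum ssp. dicoccum,10,5,5,21
subspecies,Triticum turgidum ssp. durum,15,4,2,20
subspecies,Triticum turgidum ssp. polonicum,15,3,2,0
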