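(Orodromeus_makelai,((Jeholosaurus_shangyuanensis,(Changchunsaurus_parvus,Haya_griva)),(Hypsilophodon_foxii,((Thescelosaurus_neglectus,Parksosaurus_warreni),(Gasparinisaura_cincosaltensis,(Talenkauen_santacrucensis,((Rhabdodon_sp,((Mochlodon_suessi,Mochlodon_vorosi),(Zalmoxes_robustus,Zalmoxes_shqiperorum))),((Tenontosaurus_tilletti,Tenontosaurus_dossi),((Callovosaurus_leedsi,(Dysalotosaurus_lettowvorbecki,(Dryosaurus_altus,(Valdosaurus_canaliculatus,Elrhazosaurus_nigeriensis)))),(Camptosaurus_dispar,(Cumnoria_prestwichii,(Uteodon_aphanoecetes,Planicoxa_venenica))))))))))));
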