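taxon;max_femur_mm;log10_femur;notes;status;formation;age_Ma
Orodromeus_makelai;170;2,230448921;estimate;adult;Two Medicine Formation, middle Campanian;76
Haya_griva;169;2,227886705;;?;Javkhlant Formation, Santonian;84,5
Changchunsaurus_parvus;157;2,195899652;estimate;?;Quantou Formation, Aptian-Albian;109
Jeholosaurus_shangyuanensis;135;2,130333768;;?;Yixian Formation, early Aptian;122
Hypsilophodon_foxii;200;2,301029996;;?;Wessex Formation, Barremian;127,5
Gasparinisaura_cincosaltensis;160;2,204119983;;subadult;Anacleto Formation, early Campanian;80
Thescelosaurus_neglectus;448;2,651278014;;?;Lance and Hell Creek Formations, late Maastrichtian;66
Parksosaurus_warreni;270;2,431363764;;?;Horseshoe Canyon Formation, early Maastrichtian;69
Talenkauen_santacrucensis;500;2,698970004;;?;Pari Aike Formation, early Maastrichtian;69
Rhabdodon_priscus;600;2,77815125;;?;Campanian-Maastrichtian of Spain + France;71
Rhabdodon_sp;820;2,913813852;;adult;Campanian-Maastrichtian of Spain + France;71
Rhabdodon_small;210;2,322219295;;adult;Campanian-Maastrichtian of Spain + France;71
Mochlodon_suessi;194;2,28780173;;adult;Grunbach Formation, early Campanian;80
Mochlodon_vorosi;240;2,380211242;;adult;Csehbanya Formation, Santonian;84,5
Zalmoxes_shqiperorum;333;2,522444234;;subadult;Densus Ciula Formation, late Maastrichtian;66
Zalmoxes_robustus;320;2,505149978;;subadult;Densus Ciula Formation, late Maastrichtian;66
Tenontosaurus_tilletti;580;2,763427994;;subadult;Cloverly Formation, late Aptian-middle Albian;110
Tenontosaurus_dossi;577;2,761175813;;?;Twin Mountains Formation, Aptian;118,5
Dryosaurus_altus;490;2,69019608;;subadult;Morrison Formation, Kimmeridgian-Tithonian;150,5
Callovosaurus_leedsi;280;2,447158031;;?;Oxford Clay Formation, Callovian;163
Dysalotosaurus_lettowvorbecki;350;2,544068044;;adult;Tendaguru Formation, Kimmeridgian;153
Valdosaurus_canaliculatus;432;2,635483747;;?;Wessex Formation, Barremian;127,5
Elrhazosaurus_nigeriensis;162;2,209515015;;?;Elrhaz Formation, Aptian;115
Camptosaurus_dispar;590;2,770852012;;?;Morrison Formation, Kimmeridgian-Tithonian;150,5
Uteodon_aphanoecetes;430;2,633468456;;?;Morrison Formation, Kimmeridgian-Tithonian;150,5
Cumnoria_prestwichii;420;2,62324929;;?;Kimmeridge Clay, Kimmeridgian;153
Planicoxa_venenica;520;2,716003344;;?;Cedar Mountain Formation, Barremian;127,5
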