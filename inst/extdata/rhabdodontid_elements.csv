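species;specimen;element;element_length_mm;element_estimated;femur_length_mm;femur_estimated;body_length_m;stage
Mochlodon_vorosi;MTM 2012.25.1;femur;217;no;217;no;1,6;late juvenile
Mochlodon_vorosi;MTM 2012.26.1;tibia;179;yes;192;yes;1,4;late juvenile
Mochlodon_vorosi;MTM V 2010.126.1;femur;160;yes;160;yes;1,2;subadult
Mochlodon_vorosi;MTM V 01.101;tibia;148;yes;159;yes;1,2;adult
Mochlodon_vorosi;MTM 2012.23.1;humerus;156;no;240;yes;1,8;adult
Mochlodon_vorosi;MTM V 01.225;femur;218;yes;218;yes;1,6;adult
Mochlodon_suessi;PIUW 3518;scapula;162;yes;225;yes;1,6;late juvenile
Mochlodon_suessi;PIUW 3517;radius;82;yes;174;yes;1,3;juvenile
Mochlodon_suessi;PIUW 2349/III;femur;105;yes;105;yes;0,8;juvenile
Mochlodon_suessi;PIUW 2349/35;tibia;181;yes;194;yes;1,4;adult
Zalmoxes_robustus;FGGUB R.1392;humerus;201;yes;308;yes;2,3;late juvenile
Zalmoxes_robustus;FGGUB R.1382;femur;280;yes;280;yes;2;subadult
Zalmoxes_robustus;FGGUB R.1002;femur;320;yes;320;yes;2,4;subadult
Zalmoxes_shqiperorum;FGGUB R.1088;femur;164;yes;164;yes;1,2;juvenile
Zalmoxes_shqiperorum;FGGUB R.1608;femur;333;no;333;no;2,5;subadult
Zalmoxes_sp;FGGUB R.6;humerus;180;yes;276;yes;2;subadult
Zalmoxes_sp;FGGUB OB 3077;humerus;255;no;392;yes;2,9;late juvenile
Rhabdodon_sp;MHN AIX PV 1999.12;humerus;352;yes;540;yes;4;juvenile
Rhabdodon_sp;MHN AIX PV 2001.12.294;humerus;236;no;362;yes;2,7;juvenile
Rhabdodon_sp;MHN AIX PV 2001.27;femur;513;yes;513;yes;3,7;late juvenile
Rhabdodon_sp;MHN AIX PV 2001.65;humerus;298;no;457;yes;3,4;juvenile
Rhabdodon_sp;MHN AIX PV 2001.113;femur;718;yes;718;yes;5,1;late juvenile
Rhabdodon_sp;MHN AIX PV 2001.A3;femur;626;yes;626;yes;4,5;juvenile
Rhabdodon_sp;MHN AIX PV 2007.4.115;femur;688;yes;688;yes;4,9;juvenile/late juvenile
Rhabdodon_sp;MHN AIX PV 2007.4.116;femur;820;yes;820;yes;5,9;adult
Rhabdodon_sp;MHN AIX PV 2008.1.11;femur;210;no;210;no;1,5;adult
Rhabdodon_sp;Mechin collection 472;humerus;326;yes;500;yes;3,7;late juvenile
Rhabdodon_sp;Mechin collection 676;femur;703;yes;703;yes;5;late juvenile
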