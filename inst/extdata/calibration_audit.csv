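"round","estimand","estimate","target","knob","stage"
1,"beta_total_during",0.0933241120696166,0.09,0.344454,"refine"
1,"beta_sex_during",-0.159680930136764,-0.17,-0.1886999,"refine"
1,"beta_nonwestern_during",-0.123589014423291,-0.14,-0.1997132,"refine"
1,"beta_iq_during",0.0578473589872694,0.07,0.0570954,"refine"
1,"beta_total_internalizing",-0.0250703572856924,-0.04,-0.1647749,"refine"
1,"r_sadness_anger",0.139636489591159,0.13,0.5527838,"refine"
1,"r_during_after",0.274232580444816,0.26,0.3589789,"refine"
1,"alpha_during",0.808287799267387,0.81,0.6711971,"refine"
1,"icc_anger",0.673889574637645,0.62,0.5713342,"refine"
2,"beta_total_during",0.0929174364839766,0.09,0.337039202225734,"refine"
2,"beta_sex_during",-0.144614905225138,-0.17,-0.195924700076927,"refine"
2,"beta_nonwestern_during",-0.183559991560722,-0.14,-0.215226463923625,"refine"
2,"beta_iq_during",0.0654759705371767,0.07,0.0640161898854714,"refine"
2,"beta_total_internalizing",-0.0460744342664378,-0.04,-0.218087481671385,"refine"
2,"r_sadness_anger",0.134834737188818,0.13,0.529568281385499,"refine"
2,"r_during_after",0.263616373982471,0.26,0.347681434685477,"refine"
2,"alpha_during",0.808785351479107,0.81,0.672506548446414,"refine"
2,"icc_anger",0.613789454722704,0.62,0.613302888672842,"refine"
3,"beta_total_during",0.0899619707645061,0.09,0.330649288204878,"refine"
3,"beta_sex_during",-0.182810243984179,-0.17,-0.215889096631639,"refine"
3,"beta_nonwestern_during",-0.157543741608735,-0.14,-0.182938736173715,"refine"
3,"beta_iq_during",0.0683626959598077,0.07,0.0666345515843096,"refine"
3,"beta_total_internalizing",-0.037610583718421,-0.04,-0.200350636068833,"refine"
3,"r_sadness_anger",0.137939257558453,0.13,0.518092017126057,"refine"
3,"r_during_after",0.259274717954477,0.26,0.344811769013549,"refine"
3,"alpha_during",0.80866764826508,0.81,0.673437336123836,"refine"
3,"icc_anger",0.647272479538858,0.62,0.608486813162757,"refine"
4,"beta_total_during",0.09600117710834,0.09,0.330733145483574,"refine"
4,"beta_sex_during",-0.178827638379414,-0.17,-0.206680614888076,"refine"
4,"beta_nonwestern_during",-0.136664676116178,-0.14,-0.170428335518668,"refine"
4,"beta_iq_during",0.0620552581657854,0.07,0.0675875641411648,"refine"
4,"beta_total_internalizing",-0.0512545391224118,-0.04,-0.2078933876115,"refine"
4,"r_sadness_anger",0.120200513251984,0.13,0.499988691223778,"refine"
4,"r_during_after",0.262924626384955,0.26,0.345390181102446,"refine"
4,"alpha_during",0.810211409684971,0.81,0.674459722026405,"refine"
4,"icc_anger",0.642362990782549,0.62,0.630322894826234,"refine"
5,"beta_total_during",0.0857530174239395,0.09,0.318168581767518,"refine"
5,"beta_sex_during",-0.171183610880401,-0.17,-0.200497200489217,"refine"
5,"beta_nonwestern_during",-0.135104133667655,-0.14,-0.172911890076136,"refine"
5,"beta_iq_during",0.0687288165344526,0.07,0.0726538221896048,"refine"
5,"beta_total_internalizing",-0.0445602414286196,-0.04,-0.179158439606266,"refine"
5,"r_sadness_anger",0.119880054455498,0.13,0.524061673881447,"refine"
5,"r_during_after",0.253761008711188,0.26,0.34307986981363,"refine"
5,"alpha_during",0.812134453195552,0.81,0.674297226086688,"refine"
5,"icc_anger",0.632677686816259,0.62,0.648757021543337,"refine"
1,"beta_total_during",0.0877335620508388,0.09,NA,"correction"
1,"beta_sex_during",-0.170979368184015,-0.17,NA,"correction"
1,"beta_nonwestern_during",-0.129277630530635,-0.14,NA,"correction"
1,"beta_iq_during",0.0697826163021523,0.07,NA,"correction"
1,"beta_total_internalizing",-0.0351498567747425,-0.04,NA,"correction"
1,"r_sadness_anger",0.139667355903021,0.13,NA,"correction"
1,"r_during_after",0.261998855728132,0.26,NA,"correction"
1,"alpha_during",0.809063801452823,0.81,NA,"correction"
1,"icc_anger",0.625513011727696,0.62,NA,"correction"
2,"beta_total_during",0.0899932340581146,0.09,NA,"correction"
2,"beta_sex_during",-0.164598332293998,-0.17,NA,"correction"
2,"beta_nonwestern_during",-0.148563447902918,-0.14,NA,"correction"
2,"beta_iq_during",0.0759255282886678,0.07,NA,"correction"
2,"beta_total_internalizing",-0.0419120842750621,-0.04,NA,"correction"
2,"r_sadness_anger",0.13040230442762,0.13,NA,"correction"
2,"r_during_after",0.255279968526876,0.26,NA,"correction"
2,"alpha_during",0.808920575549537,0.81,NA,"correction"
2,"icc_anger",0.594773661483829,0.62,NA,"correction"
3,"beta_total_during",0.0898112985655603,0.09,NA,"correction"
3,"beta_sex_during",-0.175967144297581,-0.17,NA,"correction"
3,"beta_nonwestern_during",-0.155279257922204,-0.14,NA,"correction"
3,"beta_iq_during",0.0667716168349578,0.07,NA,"correction"
3,"beta_total_internalizing",-0.0373357244238661,-0.04,NA,"correction"
3,"r_sadness_anger",0.125694961114791,0.13,NA,"correction"
3,"r_during_after",0.255220056174464,0.26,NA,"correction"
3,"alpha_during",0.808771740263627,0.81,NA,"correction"
3,"icc_anger",0.614283814953701,0.62,NA,"correction"
4,"beta_total_during",0.0864758836414615,0.09,NA,"verification"
4,"beta_sex_during",-0.179602075372608,-0.17,NA,"verification"
4,"beta_nonwestern_during",-0.134183493577136,-0.14,NA,"verification"
4,"beta_iq_during",0.0735136915396457,0.07,NA,"verification"
4,"beta_total_internalizing",-0.0365201496603752,-0.04,NA,"verification"
4,"r_sadness_anger",0.132256402886096,0.13,NA,"verification"
4,"r_during_after",0.261959390280918,0.26,NA,"verification"
4,"alpha_during",0.809396309310445,0.81,NA,"verification"
4,"icc_anger",0.589548486209418,0.62,NA,"verification"
5,"beta_total_during",0.0890754259839669,0.09,NA,"shipped_config"
5,"beta_sex_during",-0.161458122161137,-0.17,NA,"shipped_config"
5,"beta_nonwestern_during",-0.137485779354622,-0.14,NA,"shipped_config"
5,"beta_iq_during",0.0668608765977286,0.07,NA,"shipped_config"
5,"beta_total_internalizing",-0.0428764777078192,-0.04,NA,"shipped_config"
5,"r_sadness_anger",0.131906911841013,0.13,NA,"shipped_config"
5,"r_during_after",0.260457646306274,0.26,NA,"shipped_config"
5,"alpha_during",0.80965676635665,0.81,NA,"shipped_config"
5,"icc_anger",0.648965640415047,0.62,NA,"shipped_config"
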