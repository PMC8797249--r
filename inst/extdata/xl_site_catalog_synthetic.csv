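"rrna","position","nucleotide","previously_mapped","low_dntp_validated","human_counterpart"
"18S",70,"C",TRUE,FALSE,"Cm72"
"18S",75,"U",TRUE,FALSE,"Um77"
"18S",225,"U",TRUE,FALSE,"Um227"
"18S",252,"U",FALSE,FALSE,""
"18S",275,"A",TRUE,FALSE,"Am277"
"18S",300,"U",TRUE,FALSE,"Um302"
"18S",340,"G",TRUE,FALSE,"Gm342"
"18S",393,"U",TRUE,FALSE,"Um395"
"18S",430,"G",TRUE,FALSE,"Gm432"
"18S",477,"A",TRUE,FALSE,"Am479"
"18S",485,"U",TRUE,FALSE,"Um487"
"18S",525,"A",TRUE,FALSE,"Am527"
"18S",540,"U",TRUE,FALSE,"Um542"
"18S",555,"A",TRUE,FALSE,"Am557"
"18S",635,"C",TRUE,FALSE,"Cm637"
"18S",700,"C",TRUE,FALSE,"Cm702"
"18S",710,"C",TRUE,FALSE,"Cm712"
"18S",760,"C",TRUE,FALSE,"Cm762"
"18S",820,"A",TRUE,FALSE,"Am822"
"18S",830,"A",TRUE,FALSE,"Am832"
"18S",890,"C",TRUE,FALSE,"Cm892"
"18S",910,"A",TRUE,FALSE,"Am912"
"18S",940,"C",TRUE,FALSE,"Cm942"
"18S",1045,"U",TRUE,FALSE,"Um1047"
"18S",1070,"G",TRUE,FALSE,"Gm1072"
"18S",1175,"G",TRUE,FALSE,"Gm1177"
"18S",1240,"C",TRUE,FALSE,"Cm1242"
"18S",1410,"G",TRUE,FALSE,"Gm1412"
"18S",1555,"G",TRUE,FALSE,"Gm1557"
"18S",1700,"A",TRUE,FALSE,"Am1702"
"18S",1705,"C",TRUE,FALSE,"Cm1707"
"18S",1720,"G",TRUE,FALSE,"Gm1722"
"18S",1740,"G",TRUE,FALSE,"Gm1742"
"18S",1761,"U",TRUE,FALSE,"Um1763"
"5.8S",14,"U",TRUE,FALSE,"Um14"
"5.8S",75,"G",TRUE,FALSE,"Gm75"
"28S",158,"U",TRUE,FALSE,"Um638"
"28S",228,"U",TRUE,FALSE,"Um708"
"28S",368,"G",TRUE,FALSE,"Gm848"
"28S",393,"A",FALSE,TRUE,"Am873"
"28S",395,"A",FALSE,TRUE,"Am875"
"28S",432,"G",TRUE,FALSE,""
"28S",480,"G",TRUE,FALSE,"Gm960"
"28S",774,"U",TRUE,FALSE,"Um1254"
"28S",795,"G",TRUE,FALSE,"Gm1275"
"28S",907,"G",TRUE,FALSE,"Gm1387"
"28S",928,"A",TRUE,FALSE,"Am1408"
"28S",935,"A",TRUE,FALSE,"Am1415"
"28S",942,"U",TRUE,FALSE,"Um1422"
"28S",949,"C",TRUE,FALSE,"Cm1429"
"28S",960,"A",FALSE,TRUE,"Am1440"
"28S",963,"A",TRUE,TRUE,"Am1443"
"28S",977,"C",TRUE,TRUE,"Cm1457"
"28S",1005,"G",TRUE,FALSE,"Gm1485"
"28S",1040,"U",TRUE,FALSE,"Um1520"
"28S",1068,"C",TRUE,FALSE,"Cm1548"
"28S",1113,"C",TRUE,FALSE,""
"28S",1173,"C",TRUE,FALSE,"Cm1653"
"28S",1202,"C",FALSE,FALSE,"Cm1682"
"28S",1257,"C",TRUE,FALSE,"Cm1737"
"28S",1286,"G",FALSE,TRUE,"Gm1766"
"28S",1525,"C",TRUE,FALSE,"Cm2005"
"28S",1803,"G",TRUE,FALSE,"Gm2283"
"28S",1848,"A",TRUE,FALSE,"Am2328"
"28S",1850,"C",TRUE,FALSE,"Cm2330"
"28S",1886,"A",FALSE,TRUE,"Am2366"
"28S",1907,"C",TRUE,FALSE,"Cm2387"
"28S",2062,"C",TRUE,FALSE,"Cm2542"
"28S",2101,"A",FALSE,FALSE,"Am2581"
"28S",2309,"A",TRUE,TRUE,"Am2789"
"28S",2326,"C",TRUE,TRUE,"Cm2806"
"28S",2337,"A",TRUE,FALSE,"Am2817"
"28S",2359,"U",TRUE,TRUE,"Um2839"
"28S",2370,"U",TRUE,FALSE,"Um2850"
"28S",2383,"C",TRUE,TRUE,"Cm2863"
"28S",2398,"G",FALSE,TRUE,"Gm2878"
"28S",2642,"G",FALSE,FALSE,"Gm3122"
"28S",2869,"A",TRUE,TRUE,"Am3349"
"28S",2875,"A",TRUE,TRUE,"Am3355"
"28S",2895,"G",TRUE,FALSE,"Gm3375"
"28S",2911,"A",TRUE,TRUE,"Am3391"
"28S",2936,"A",TRUE,TRUE,"Am3416"
"28S",2943,"G",FALSE,TRUE,"Gm3423"
"28S",3018,"A",TRUE,FALSE,"Am3498"
"28S",3020,"C",TRUE,FALSE,"Cm3500"
"28S",3050,"G",FALSE,TRUE,"Gm3530"
"28S",3273,"C",TRUE,FALSE,"Cm3753"
"28S",3305,"G",FALSE,TRUE,"Gm3785"
"28S",3315,"U",TRUE,FALSE,"Um3795"
"28S",3385,"G",TRUE,FALSE,"Gm3865"
"28S",3497,"A",TRUE,FALSE,"Am3977"
"28S",3501,"G",FALSE,TRUE,"Gm3981"
"28S",3534,"G",TRUE,TRUE,""
"28S",3565,"C",TRUE,FALSE,"Cm4045"
"28S",3603,"G",TRUE,TRUE,"Gm4083"
"28S",3680,"A",TRUE,FALSE,"Am4160"
"28S",3746,"G",TRUE,FALSE,"Gm4226"
"28S",3749,"A",TRUE,FALSE,"Am4229"
"28S",3777,"U",TRUE,FALSE,"Um4257"
"28S",3868,"G",TRUE,FALSE,"Gm4348"
"28S",3888,"U",FALSE,FALSE,"Um4368"
"28S",3910,"A",TRUE,FALSE,"Am4390"
"28S",4013,"C",TRUE,TRUE,""
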