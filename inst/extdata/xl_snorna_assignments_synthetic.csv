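"rrna","position","label","snorna_id","rfam_family"
"18S",70,"Cm70","XLsno-CD-001",""
"18S",75,"Um75","XLsno-CD-002","SNORD101"
"18S",225,"Um225","XLsno-CD-003",""
"18S",252,"Um252","XLsno-CD-004",""
"18S",275,"Am275","XLsno-CD-005","SNORD102"
"18S",300,"Um300","XLsno-CD-006","SNORD103"
"18S",340,"Gm340","XLsno-CD-007",""
"18S",393,"Um393","XLsno-CD-008",""
"18S",430,"Gm430","XLsno-CD-009","SNORD104"
"18S",477,"Am477","XLsno-CD-010",""
"18S",485,"Um485","XLsno-CD-011","SNORD105"
"18S",525,"Am525","XLsno-CD-012","SNORD106"
"18S",540,"Um540","XLsno-CD-013","SNORD107"
"18S",555,"Am555","XLsno-CD-014","SNORD108"
"18S",635,"Cm635","XLsno-CD-015","SNORD109"
"18S",700,"Cm700","XLsno-CD-016",""
"18S",710,"Cm710","XLsno-CD-017",""
"18S",760,"Cm760","XLsno-CD-018","SNORD110"
"18S",820,"Am820","XLsno-CD-019",""
"18S",830,"Am830","XLsno-CD-020","SNORD111"
"18S",890,"Cm890","XLsno-CD-021",""
"18S",910,"Am910","XLsno-CD-022",""
"18S",940,"Cm940","XLsno-CD-023",""
"18S",1045,"Um1045","XLsno-CD-024",""
"18S",1070,"Gm1070","XLsno-CD-025","SNORD112"
"18S",1175,"Gm1175","XLsno-CD-026",""
"18S",1240,"Cm1240","XLsno-CD-027","SNORD113"
"18S",1410,"Gm1410","XLsno-CD-028","SNORD114"
"18S",1555,"Gm1555","XLsno-CD-029","SNORD115"
"18S",1700,"Am1700","XLsno-CD-030","SNORD116"
"18S",1705,"Cm1705","XLsno-CD-031","SNORD117"
"18S",1720,"Gm1720","XLsno-CD-032",""
"18S",1740,"Gm1740","XLsno-CD-033","SNORD118"
"18S",1761,"Um1761","XLsno-CD-034","SNORD119"
"5.8S",14,"Um14","XLsno-CD-035","SNORD120"
"5.8S",75,"Gm75","XLsno-CD-036","SNORD121"
"28S",158,"Um158","XLsno-CD-037",""
"28S",228,"Um228","XLsno-CD-038","SNORD122"
"28S",368,"Gm368","XLsno-CD-039",""
"28S",393,"Am393","XLsno-CD-040",""
"28S",395,"Am395","XLsno-CD-041",""
"28S",432,"Gm432","XLsno-CD-042",""
"28S",480,"Gm480","XLsno-CD-043","SNORD123"
"28S",774,"Um774","XLsno-CD-044",""
"28S",795,"Gm795","XLsno-CD-045",""
"28S",907,"Gm907","XLsno-CD-046","SNORD124"
"28S",928,"Am928","XLsno-CD-047",""
"28S",935,"Am935","XLsno-CD-048","SNORD125"
"28S",942,"Um942","XLsno-CD-049","SNORD126"
"28S",949,"Cm949","XLsno-CD-050",""
"28S",960,"Am960","XLsno-CD-051",""
"28S",963,"Am963","XLsno-CD-052","SNORD127"
"28S",977,"Cm977","XLsno-CD-053","SNORD128"
"28S",1005,"Gm1005","XLsno-CD-054",""
"28S",1040,"Um1040","XLsno-CD-055","SNORD129"
"28S",1068,"Cm1068","XLsno-CD-056",""
"28S",1113,"Cm1113","XLsno-CD-057","SNORD130"
"28S",1173,"Cm1173","XLsno-CD-058","SNORD131"
"28S",1202,"Cm1202","XLsno-CD-059",""
"28S",1257,"Cm1257","XLsno-CD-060","SNORD132"
"28S",1286,"Gm1286","XLsno-CD-061",""
"28S",1525,"Cm1525","XLsno-CD-062",""
"28S",1803,"Gm1803","XLsno-CD-063","SNORD133"
"28S",1848,"Am1848","XLsno-CD-064","SNORD134"
"28S",1850,"Cm1850","XLsno-CD-065","SNORD135"
"28S",1886,"Am1886","XLsno-CD-066",""
"28S",1907,"Cm1907","XLsno-CD-067","SNORD136"
"28S",2062,"Cm2062","XLsno-CD-068",""
"28S",2101,"Am2101","XLsno-CD-069",""
"28S",2309,"Am2309","XLsno-CD-070","SNORD137"
"28S",2326,"Cm2326","XLsno-CD-071","SNORD138"
"28S",2337,"Am2337","XLsno-CD-072","SNORD139"
"28S",2359,"Um2359","XLsno-CD-073","SNORD140"
"28S",2370,"Um2370","XLsno-CD-074",""
"28S",2383,"Cm2383","XLsno-CD-075","SNORD141"
"28S",2398,"Gm2398","XLsno-CD-076",""
"28S",2642,"Gm2642","XLsno-CD-077",""
"28S",2869,"Am2869","XLsno-CD-078","SNORD142"
"28S",2875,"Am2875","XLsno-CD-079",""
"28S",2895,"Gm2895","XLsno-CD-080",""
"28S",2911,"Am2911","XLsno-CD-081","SNORD143"
"28S",2936,"Am2936","XLsno-CD-082",""
"28S",2943,"Gm2943","XLsno-CD-083",""
"28S",3018,"Am3018","XLsno-CD-084","SNORD144"
"28S",3020,"Cm3020","XLsno-CD-085","SNORD145"
"28S",3050,"Gm3050","XLsno-CD-086",""
"28S",3273,"Cm3273","XLsno-CD-087","SNORD146"
"28S",3305,"Gm3305","XLsno-CD-088",""
"28S",3315,"Um3315","XLsno-CD-089",""
"28S",3385,"Gm3385","XLsno-CD-090","SNORD147"
"28S",3497,"Am3497","XLsno-CD-091","SNORD148"
"28S",3501,"Gm3501","XLsno-CD-092",""
"28S",3534,"Gm3534","XLsno-CD-093",""
"28S",3565,"Cm3565","XLsno-CD-094",""
"28S",3603,"Gm3603","XLsno-CD-095",""
"28S",3680,"Am3680","XLsno-CD-096","SNORD149"
"28S",3746,"Gm3746","XLsno-CD-097","SNORD150"
"28S",3749,"Am3749","XLsno-CD-098","SNORD151"
"28S",3777,"Um3777","XLsno-CD-099","SNORD152"
"28S",3868,"Gm3868","XLsno-CD-100","SNORD153"
"28S",3888,"Um3888","XLsno-CD-101",""
"28S",3910,"Am3910","XLsno-CD-102","SNORD154"
"28S",4013,"Cm4013","XLsno-CD-103",""
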