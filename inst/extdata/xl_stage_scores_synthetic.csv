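"rrna","position","label","stage_2","stage_10","stage_16","stage_23","stage_32","stage_45"
"18S",70,"Cm70",0.964,0.865,0.88,0.903,0.869,0.94
"18S",75,"Um75",0.918,0.944,0.945,0.85,0.946,0.959
"18S",225,"Um225",0.858,0.895,0.918,0.888,0.892,0.95
"18S",252,"Um252",0.506,0.549,0.559,0.636,0.646,0.498
"18S",275,"Am275",0.898,0.874,0.893,0.91,0.907,0.915
"18S",300,"Um300",0.868,0.952,0.912,0.936,0.885,0.9
"18S",340,"Gm340",0.877,0.935,0.896,0.957,0.912,0.927
"18S",393,"Um393",0.928,0.901,0.857,0.949,0.918,0.549
"18S",430,"Gm430",0.877,0.861,0.906,0.909,0.955,0.936
"18S",477,"Am477",0.898,0.938,0.939,0.936,0.888,0.476
"18S",485,"Um485",0.872,0.915,0.944,0.868,0.936,0.946
"18S",525,"Am525",0.889,0.883,0.921,0.877,0.896,0.956
"18S",540,"Um540",0.928,0.882,0.936,0.877,0.85,0.878
"18S",555,"Am555",0.859,0.874,0.917,0.922,0.927,0.54
"18S",635,"Cm635",0.951,0.927,0.91,0.94,0.891,0.882
"18S",700,"Cm700",0.946,0.891,0.965,0.87,0.881,0.937
"18S",710,"Cm710",0.901,0.882,0.877,0.908,0.903,0.874
"18S",760,"Cm760",0.512,0.592,0.552,0.539,0.412,0.561
"18S",820,"Am820",0.859,0.885,0.868,0.869,0.862,0.894
"18S",830,"Am830",0.851,0.876,0.895,0.877,0.907,0.855
"18S",890,"Cm890",0.895,0.9,0.916,0.905,0.959,0.872
"18S",910,"Am910",0.947,0.95,0.888,0.966,0.958,0.907
"18S",940,"Cm940",0.962,0.968,0.894,0.955,0.94,0.933
"18S",1045,"Um1045",0.953,0.919,0.941,0.958,0.911,0.903
"18S",1070,"Gm1070",0.871,0.88,0.882,0.863,0.942,0.867
"18S",1175,"Gm1175",0.883,0.891,0.931,0.953,0.876,0.905
"18S",1240,"Cm1240",0.953,0.91,0.868,0.926,0.955,0.944
"18S",1410,"Gm1410",0.869,0.891,0.955,0.853,0.889,0.946
"18S",1555,"Gm1555",0.865,0.955,0.865,0.892,0.866,0.955
"18S",1700,"Am1700",0.888,0.946,0.866,0.894,0.913,0.943
"18S",1705,"Cm1705",0.92,0.898,0.961,0.916,0.868,0.932
"18S",1720,"Gm1720",0.931,0.888,0.857,0.904,0.909,0.872
"18S",1740,"Gm1740",0.96,0.908,0.889,0.951,0.935,0.94
"18S",1761,"Um1761",0.525,0.503,0.483,0.576,0.497,0.576
"5.8S",14,"Um14",0.918,0.934,0.871,0.861,0.922,0.543
"5.8S",75,"Gm75",0.939,0.865,0.965,0.869,0.932,0.953
"28S",158,"Um158",0.955,0.894,0.86,0.891,0.908,0.968
"28S",228,"Um228",0.95,0.853,0.921,0.877,0.867,0.886
"28S",368,"Gm368",0.868,0.86,0.915,0.903,0.953,0.945
"28S",393,"Am393",0.95,0.913,0.92,0.858,0.936,0.541
"28S",395,"Am395",0.873,0.945,0.949,0.876,0.961,0.968
"28S",432,"Gm432",0.957,0.911,0.857,0.873,0.871,0.887
"28S",480,"Gm480",0.905,0.922,0.881,0.893,0.861,0.898
"28S",774,"Um774",0.898,0.873,0.885,0.945,0.936,0.938
"28S",795,"Gm795",0.895,0.94,0.918,0.882,0.879,0.872
"28S",907,"Gm907",0.94,0.966,0.868,0.863,0.965,0.968
"28S",928,"Am928",0.912,0.966,0.884,0.938,0.881,0.913
"28S",935,"Am935",0.893,0.945,0.937,0.88,0.877,0.955
"28S",942,"Um942",0.882,0.857,0.95,0.942,0.932,0.89
"28S",949,"Cm949",0.945,0.959,0.885,0.852,0.915,0.869
"28S",960,"Am960",0.896,0.932,0.909,0.964,0.921,0.936
"28S",963,"Am963",0.411,0.504,0.461,0.541,0.53,0.561
"28S",977,"Cm977",0.906,0.931,0.951,0.941,0.935,0.919
"28S",1005,"Gm1005",0.851,0.885,0.895,0.965,0.854,0.919
"28S",1040,"Um1040",0.917,0.962,0.893,0.857,0.869,0.882
"28S",1068,"Cm1068",0.86,0.919,0.882,0.855,0.866,0.852
"28S",1113,"Cm1113",0.947,0.922,0.932,0.88,0.857,0.904
"28S",1173,"Cm1173",0.916,0.951,0.951,0.911,0.887,0.852
"28S",1202,"Cm1202",0.865,0.911,0.919,0.859,0.947,0.939
"28S",1257,"Cm1257",0.853,0.852,0.929,0.945,0.923,0.887
"28S",1286,"Gm1286",0.893,0.89,0.964,0.938,0.876,0.915
"28S",1525,"Cm1525",0.889,0.915,0.91,0.857,0.899,0.626
"28S",1803,"Gm1803",0.904,0.943,0.936,0.894,0.921,0.877
"28S",1848,"Am1848",0.591,0.614,0.502,0.646,0.556,0.489
"28S",1850,"Cm1850",0.509,0.423,0.412,0.45,0.454,0.488
"28S",1886,"Am1886",0.936,0.937,0.892,0.913,0.933,0.938
"28S",1907,"Cm1907",0.856,0.923,0.942,0.899,0.917,0.485
"28S",2062,"Cm2062",0.913,0.953,0.868,0.937,0.917,0.967
"28S",2101,"Am2101",0.87,0.965,0.94,0.896,0.901,0.886
"28S",2309,"Am2309",0.965,0.961,0.921,0.852,0.895,0.907
"28S",2326,"Cm2326",0.892,0.864,0.899,0.852,0.969,0.865
"28S",2337,"Am2337",0.897,0.884,0.891,0.861,0.863,0.581
"28S",2359,"Um2359",0.918,0.887,0.86,0.969,0.893,0.876
"28S",2370,"Um2370",0.955,0.963,0.922,0.968,0.866,0.941
"28S",2383,"Cm2383",0.959,0.912,0.96,0.962,0.942,0.859
"28S",2398,"Gm2398",0.945,0.856,0.894,0.898,0.948,0.96
"28S",2642,"Gm2642",0.958,0.895,0.853,0.893,0.949,0.893
"28S",2869,"Am2869",0.89,0.869,0.869,0.861,0.956,0.938
"28S",2875,"Am2875",0.957,0.944,0.878,0.881,0.947,0.964
"28S",2895,"Gm2895",0.56,0.402,0.546,0.554,0.613,0.642
"28S",2911,"Am2911",0.517,0.631,0.641,0.591,0.538,0.613
"28S",2936,"Am2936",0.94,0.911,0.967,0.893,0.875,0.87
"28S",2943,"Gm2943",0.85,0.889,0.967,0.934,0.901,0.896
"28S",3018,"Am3018",0.418,0.595,0.548,0.524,0.452,0.6
"28S",3020,"Cm3020",0.928,0.89,0.905,0.918,0.881,0.456
"28S",3050,"Gm3050",0.852,0.866,0.886,0.923,0.97,0.868
"28S",3273,"Cm3273",0.969,0.884,0.877,0.87,0.932,0.909
"28S",3305,"Gm3305",0.967,0.929,0.907,0.949,0.895,0.86
"28S",3315,"Um3315",0.913,0.945,0.954,0.864,0.861,0.959
"28S",3385,"Gm3385",0.896,0.922,0.868,0.93,0.873,0.883
"28S",3497,"Am3497",0.892,0.901,0.877,0.9,0.967,0.898
"28S",3501,"Gm3501",0.888,0.913,0.878,0.949,0.891,0.888
"28S",3534,"Gm3534",0.905,0.878,0.912,0.934,0.91,0.497
"28S",3565,"Cm3565",0.538,0.409,0.512,0.596,0.638,0.641
"28S",3603,"Gm3603",0.922,0.857,0.894,0.947,0.866,0.853
"28S",3680,"Am3680",0.916,0.878,0.941,0.945,0.895,0.506
"28S",3746,"Gm3746",0.897,0.942,0.932,0.949,0.863,0.507
"28S",3749,"Am3749",0.927,0.942,0.876,0.933,0.946,0.95
"28S",3777,"Um3777",0.862,0.864,0.909,0.968,0.899,0.883
"28S",3868,"Gm3868",0.928,0.915,0.97,0.948,0.949,0.862
"28S",3888,"Um3888",0.95,0.87,0.88,0.852,0.968,0.903
"28S",3910,"Am3910",0.914,0.864,0.901,0.909,0.939,0.925
"28S",4013,"Cm4013",0.903,0.903,0.884,0.859,0.927,0.872
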