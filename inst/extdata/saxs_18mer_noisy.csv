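"q","intensity","noise_sd"
0.01,326.501514880826,2.04612241307054
0.02,323.961001369967,2.0370491427658
0.03,320.299825300478,2.02201753807665
0.04,319.787803758211,2.00116211229374
0.05,309.762070629908,1.97466869389395
0.06,304.263909707896,1.94277198443385
0.07,299.294591979052,1.90575248633006
0.08,294.673128043244,1.86393284956753
0.09,288.670247614577,1.81767369544604
0.1,276.940606024314,1.76736898350224
0.11,269.501032959982,1.71344099459117
0.12,265.441721310986,1.65633500865815
0.13,251.845906471514,1.59651375988831
0.14,241.719002116879,1.53445175462103
0.15,233.24294381843,1.47062953862251
0.16,222.070270972442,1.40552800001216
0.17,209.653655367339,1.33962279235752
0.18,202.575709980025,1.27337895923432
0.19,188.772749704734,1.20724583696705
0.2,182.048220214203,1.14165230642049
0.21,170.544228491391,1.07700245772539
0.22,159.046264626205,1.01367172383382
0.23,149.720846146311,0.952003529972323
0.24,140.853520663588,0.892306496565796
0.25,134.123046007214,0.83485222322748
0.26,124.012943681541,0.77987367114071
0.27,114.448366347353,0.727564150789658
0.28,105.689070380819,0.678076911722488
0.29,99.1940736466877,0.63152532103875
0.3,92.686082628979,0.587983607763226
0.31,87.0251803235315,0.547488141368594
0.32,80.8435228189827,0.510039204592047
0.33,75.0453314212,0.475603213491359
0.34,70.3018308812168,0.444115331518734
0.35,65.8951666731435,0.415482419348761
0.36,60.9604571506624,0.389586258348936
0.37,57.5558305748707,0.366286982971983
0.38,54.457388832804,0.345426655997884
0.39,51.3563565774993,0.326832920454445
0.4,48.6034222715323,0.310322663168353
0.41,46.7164687001276,0.295705627190367
0.42,44.6913015299518,0.282787913723379
0.43,42.9194068241163,0.271375318565306
0.44,41.2009498085817,0.261276453347348
0.45,39.4035397868136,0.252305607874541
0.46,38.8793241994401,0.244285316520057
0.47,37.1409471682675,0.237048598738952
0.48,36.2493624071802,0.230440851196892
0.49,35.7187089052682,0.224321376598441
0.5,34.7157561735028,0.2185645418922
0.51,33.455643424008,0.21306056597514
0.52,32.6664669029682,0.20771594417165
0.53,31.9736734061206,0.202453523489811
0.54,31.0968354102818,0.197212248836641
0.55,30.3405234567572,0.191946605898445
0.56,29.4001413232775,0.186625791171667
0.57,28.9009549444993,0.181232643591577
0.58,27.8666242770948,0.17576237529759
0.59,26.9360581195642,0.170221141261733
0.6,25.9619140137272,0.164624488777386
0.61,25.2424046908265,0.158995728165272
0.62,24.3922624449279,0.15336426552822
0.63,23.4232279644359,0.147763937018761
0.64,22.4062100780099,0.142231381934216
0.65,21.6211808435554,0.136804489097318
0.66,20.9175747405512,0.13152094750415
0.67,20.2899687339672,0.126416928223422
0.68,19.1734641055846,0.121525920118137
0.69,18.1572645162695,0.116877737244256
0.7,17.9361473319799,0.11249771087594
0.71,17.1951843031801,0.108406074128544
0.72,16.4267440740251,0.104617542211719
0.73,16.0060597393003,0.101141086554336
0.74,15.3186785758518,0.0979798965020041
0.75,15.1885815653066,0.0951315180895651
0.76,14.640330117376,0.0925881556170838
0.77,14.2757343487237,0.0903371184784475
0.78,14.0085948877434,0.0883613929631791
0.79,13.6991240529038,0.086640316616664
0.8,13.4399457440685,0.0851503312291016
0.81,13.3763314612638,0.0838657896415481
0.82,12.9612583135553,0.0827597913060446
0.83,12.9361329502744,0.0818050218993147
0.84,12.7076297931789,0.0809745732356596
0.85,12.6512429002905,0.0802427212117998
0.86,12.5963781062279,0.0795856414907751
0.87,12.5663889427813,0.0789820450302908
0.88,12.4233265690198,0.0784137183119827
0.89,12.2862129223963,0.0778659561548732
0.9,12.3418288802651,0.0773278782177021
0.91,12.1660812537421,0.0767926236277091
0.92,12.0372064897218,0.076257421534621
0.93,12.0224784016367,0.0757235386967212
0.94,11.9738014891677,0.075196108383313
0.95,11.6989117582401,0.0746838478523746
0.96,11.7518629313279,0.0741986743683734
0.97,11.5948563868657,0.07375523210596
0.98,11.5707117413298,0.0733703442927589
0.99,11.5389365298558,0.0730624065411189
1,11.5770228005172,0.0728507384775809
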