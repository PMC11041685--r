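"mass_kda"
265.583646906096
257.5519877244
816.014019971211
264.345299451495
789.938802762127
777.652351873276
265.75873702844
784.637099826027
262.963954773983
272.645281605528
794.600713421378
260.102404845855
266.667607787197
791.615047747565
806.809536063302
273.414754967818
260.522846610942
804.65076294581
798.753954239804
811.682479905955
264.578499413362
810.74240090381
256.523283041134
274.781163625702
811.191479201414
794.99542452925
774.291234288541
269.218234249423
805.105975740118
265.766213489944
266.605139526457
262.69487671362
803.281729771987
267.366382469949
792.946371513933
258.696565942588
808.575542156482
806.238327732026
261.354194152668
771.969507992324
800.668679443212
791.896536927288
801.428651445256
258.921082893484
782.103149753022
271.571979122162
267.946467393469
806.753303235599
275.449754419754
799.454444143351
765.489180516658
802.723078744671
816.080293131118
276.748510612063
775.44181123126
259.682051813126
262.047853465455
780.589918387433
787.101679103323
794.443592171495
259.414303578266
276.628544039682
266.372930543812
796.058644013137
268.43471401477
797.996697388209
795.293459986627
273.650601943603
264.64626740315
776.929112049137
803.550631516791
791.794072692958
789.078395903154
780.365443611441
804.231579425297
264.874919065786
805.623868936479
793.662342557525
786.898187364994
817.338773361847
793.065912271403
812.517938430218
778.237163404623
789.966380495003
264.368127983366
791.164883671129
818.909179427244
797.036948543693
801.294913873398
782.371056002986
261.923480958075
813.317202953633
817.47026558697
272.438959369714
258.460533444723
276.697591047371
813.617087889643
796.973909881923
269.540378952091
781.908348365486
779.918500259619
798.182256591553
778.286388079616
800.430422989031
272.698604562298
260.303927288719
261.874448950603
266.047533902121
781.171377081013
791.287387407734
811.318703305335
270.954101294265
267.840528871284
767.8713902854
796.538860041096
814.381003222267
810.36883445664
794.356858870985
754.341519413026
266.124098651867
806.550192071468
798.130475489456
799.910415190725
804.282604566511
263.691941603157
818.291532744286
268.30061131373
259.193964841625
819.433365378436
272.202903709144
270.180777190933
770.884386293944
788.32070243218
269.178391452711
266.032426192284
802.95010021879
278.875199305795
784.348470586474
254.566228189037
801.76489220472
786.43420557585
804.513462712636
784.444088424988
277.559286933462
265.142379055094
263.262484449944
794.748461733772
270.385386947358
798.952386058015
771.474664243058
265.775435998235
809.524342089874
266.00727569283
809.122930514467
265.021351514874
265.492270925113
805.092828245435
813.235465119299
777.522484597385
265.621980317921
265.422765044475
785.296733414299
780.904036911742
787.341086798073
806.758409518767
790.760486279183
784.882609214009
800.006163463164
777.676881378476
814.079594983422
263.223890767381
800.416226288683
798.213448975958
797.396161812599
826.256024812879
784.237669740011
271.889320924044
797.903529195099
261.360045938989
265.434452441828
269.769838288158
263.537942407958
785.086832513135
799.836281974415
271.05538082897
265.409495492883
258.426566841276
258.853710892341
785.145631355657
788.993679616528
797.058281166716
269.364367745416
790.468727468847
779.635845215727
807.082126406322
801.792987737459
815.857371063026
770.567795253041
266.264188276565
272.994471828199
269.649707924433
784.122447534712
269.694121435661
783.494510277284
790.169216490907
816.338796675577
264.257587522524
810.613653919909
792.75550050039
772.26017236908
783.863087265059
780.040285241507
789.676533971823
792.036508838715
794.954248359728
264.506897732896
827.576838159439
775.296098516972
790.784382052312
267.655717403416
823.370397255224
798.811747192841
817.161975497572
257.057542771933
820.466493866736
262.128982127428
792.991477049182
779.706989617124
799.534947858417
825.872587197015
836.028661189552
780.226732669016
805.149788828709
819.544144689494
264.759888359315
264.640182775394
792.539401180893
268.978078761376
819.68620424369
808.366159952255
802.506358452008
792.585778423704
805.347664837278
788.635985233064
792.946417279993
814.887196390746
804.449224730276
801.243727857128
793.32356911239
270.749370904294
818.689185911568
783.536853909714
798.284905952999
798.182519131585
788.1763828441
260.490705304725
797.361202024455
807.854103507101
820.952680665118
766.952831332523
262.065831759871
792.433310883146
770.875971674917
261.810164223432
785.002794144573
785.876458426639
254.164155270934
800.80359903997
262.440697670869
273.882931186412
810.093905481272
258.073036831754
798.969210174201
787.93054034345
270.522102692461
798.246366986373
788.516587215029
804.391555932883
799.833794914029
794.774678806258
829.613215631299
788.957353885012
789.89188935485
257.581799311923
796.753679816889
811.599402359646
764.365506553381
793.411961465075
778.555038995733
820.39601550249
273.01857268468
267.578217136463
820.195083706223
783.568014914187
812.560993709852
788.070236460317
267.506210189746
792.625232326228
792.957794907642
806.109444545039
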