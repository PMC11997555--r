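Ch1 Amplitude,Ch2 Amplitude
8000.875784500836,8800.17379683518
1190.145733842331,1315.3617100729425
7688.903001475378,8075.961485262251
8082.151070009514,668.2294656355334
1409.0178966847375,8383.182067376978
7595.9692758389665,175.9252908538523
699.2265962465223,8098.484083208183
1057.6769729258797,7958.091152467083
8352.223291509874,1128.93444272579
1172.5445098025107,8281.969946301406
7723.621431991882,8559.16080691819
8223.73630414857,8030.656318532752
7774.483791770722,8328.095865975965
-96.92700515265369,8293.026981742772
1257.07305856352,8295.810633764615
8159.690712990018,8030.61732369479
1279.4851977288133,7567.934592241344
8208.982829575518,7678.227087902449
761.3908262353093,376.15650302553445
1431.8476425167903,1244.2079287110653
739.1727257177577,313.05083158957905
1598.1911861862823,8630.072310926093
8053.759274042183,7959.248628804887
7970.5934356612215,7826.968756664212
8010.509811690071,1341.1333588848554
1095.7283816705078,7882.891597394537
966.1476163600119,8583.841863197254
8183.608434576267,7446.221903694972
897.643601062676,1322.1724224923287
1246.3808091135338,8566.25067114321
1538.8473721839528,1839.4736271002357
1270.3314733091515,1577.9499126492296
912.1140717863968,8392.318790396626
7850.8591023029085,7633.509152748484
7987.20402620914,8396.672889422918
8034.912143824512,8395.265702424062
974.5778592249974,7348.156495598275
7793.739733705503,642.5377305678405
1031.2309089970192,7763.498578394954
633.3243209261524,7994.740752553879
8086.9835070514355,7753.714039876569
8436.67579992752,1624.8377309587868
1545.994000420033,7914.005499300966
1453.6736827791922,7821.989299285293
7635.910658647261,1223.9532928415438
1756.6644134241915,839.8715836366313
774.1262421648959,7510.002490531106
1103.13381935905,7790.767766938777
7551.217901096523,1075.4428010428087
1061.2469237453915,7836.231788811075
1691.655077053847,7549.066098836765
8068.956096458904,1356.9937144362916
1410.385279880547,657.3819000124702
888.9127095675129,7093.830074274304
8108.824326340157,1306.54882289442
7370.340218656554,8385.150927494238
1059.165829806136,8187.719032954154
935.5598355126949,8294.914065427753
1220.963516961061,7516.1894778719325
539.6506955042439,1492.4311804564652
904.5090991113481,1261.4738142686865
862.5853346349315,1254.1641689009234
1211.7859116369968,8215.08691961983
697.5299666948589,8472.076527629324
-16.307031877728605,371.4857833976246
8243.363332362494,7982.722685790775
7818.104766265035,8054.790627483767
8291.506515723879,1518.9299333649838
1215.9520059354788,8740.306476584958
1370.0030977946988,7765.517910832383
1357.9402033914264,1309.458667804785
928.1484900555195,916.649160838165
463.1657761971675,873.8855520633275
674.043002704813,983.6101575626913
1228.617559632303,7913.8033311092295
8012.175339036689,7985.157137411928
751.8636675179105,7975.6705254920435
364.70864631292113,705.5312987344289
7625.824283667682,7783.2240105935725
952.5152951559896,8263.471738989947
1265.9917084837366,8122.399411713881
1095.907528745326,7759.74196736342
1545.5223891648002,722.1969644713947
1089.4146969383653,8234.223939687248
8244.162046232761,643.5741016417976
843.2777818445554,8139.1827369423545
7688.39968256821,7907.015284476681
1025.575224377399,8094.003208686409
1438.8613940051614,7803.4447001364715
9013.277304805391,1399.3704900646444
724.0511416367924,7991.91485083313
8321.471541682537,7946.513521735319
1663.1150946484067,8154.52126181671
833.182693844104,7918.02135514053
8135.218910051664,7659.416234153224
1282.0507145689555,8057.860879970702
8525.007282759121,7761.427120950167
508.38416377831635,8378.703306223882
7490.321449282304,7391.706095447202
1054.6128599159651,1221.891060815776
1284.4811377922294,1310.1011221411761
7747.049460472482,7707.524892653606
872.835894958882,8319.61504789896
1427.0006649443662,8006.347456410312
1636.9020659353523,8893.40339370056
8179.743639682177,668.7869943688095
956.7382251156429,7163.983240732306
1286.1897004308435,8706.41087945958
1071.9338679764937,967.4434516228662
8527.43347439268,7569.843410913891
1155.8578920211983,1028.924401842816
465.9332125082318,1178.106110620587
7356.166565693753,7625.863489849125
652.0770307921669,8355.590722601819
2172.2138481347556,7774.2116302879895
7831.367915924338,662.0876425330503
7984.068111564357,730.4631632561827
1015.2506753069515,7846.495157501118
1417.0242047583454,7907.890674611266
743.4689580851823,151.3163698992015
7572.613745470082,7677.3775913479285
1079.9405432656972,7818.8433003764585
8155.264832776911,7693.757388364887
728.2197386406485,7215.105372369417
9062.868311297905,7852.750173668754
934.6997891397627,8673.999890039331
590.2544055037101,7544.991425591729
8274.369686254171,8314.908544284877
7218.874201525559,8292.410106991016
7854.149592084669,1133.0067933673329
1033.4806594472052,658.0990445964892
750.0114349242722,7535.875866728596
1535.3698106514753,7900.938961648803
808.7049360244771,8252.003772301243
8452.495562414188,1091.6197755372852
7393.990868744252,8811.136048711469
8548.120712740138,7941.032855690249
169.93818944938482,7663.803456919389
1003.4618816254052,7266.8123659391285
1177.1788474260702,8065.52240000481
7738.610384560262,7551.202158260392
363.6563963900643,7805.451844229411
1130.9755801738409,8131.952070722908
1014.0872429297788,7569.0720307119655
1289.8220807581956,7842.428707056872
8605.229995625403,8630.214440391785
539.7624178776231,8271.642322414265
1191.55559281047,7727.19717934152
541.8005699344864,7848.522366786621
1518.6316280598285,8013.4790522214425
836.4233043406722,8288.208056276198
1318.5973522470363,8162.160247134227
8289.169290624817,8174.4277427866455
696.8115625405153,7917.187084539433
7184.036136645646,7914.608864986832
796.4454492721621,1096.3954342987054
1291.654945879593,7320.344543337249
1326.1063832645266,8611.211452049623
1469.870214636604,7880.838499909914
558.9691172975523,8206.93016168215
901.8606093833858,8536.983625348816
8219.991550016188,1785.5655396784928
7700.265299150889,7746.803426495025
739.1544145543775,7958.952288242946
8176.726853066969,7332.14984327395
7788.351060383461,8103.156216394161
1068.5351086310081,966.7790564566403
1046.6060228527615,8209.504332295459
1236.2147257528568,8068.966331006268
715.6588248882133,7258.427542986327
8697.640935159949,7600.543796651105
7830.109788996129,7618.5477180077505
835.0059091455471,8324.327047694738
7940.30197787016,410.70903659878195
1019.6193340288164,8329.706946993185
948.0304224300588,8613.277532448614
916.4551772144539,772.8794088745801
814.8413743835181,931.747384764683
8930.172253280425,8456.734240507167
663.028563407293,424.2906582047236
1069.5696848215662,511.38992711708664
7902.126245587918,8332.835145999748
1105.782693455731,257.2162686522058
8012.383395746327,7641.67456930831
1611.092499690112,8316.292164422524
8156.174265044667,8069.462431963562
7354.022184789692,8055.06591398097
8328.426955558627,7611.261739290618
7947.052006128555,8724.375672396674
1482.4529642459704,8595.26541174782
1005.7350598112175,8004.729905730309
1297.386309435789,506.5808778230563
1357.4854008657617,7455.735103630367
542.4591997354664,1193.2407464727905
1567.349132553681,7889.385497798192
1220.774263410578,7873.977915937364
834.277831491411,7865.525608590528
936.0884086331947,8594.996081267192
7459.545950167338,1205.221498437983
7926.768605251379,7877.001096233197
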