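"freq_hz","z_real_ohm","z_imag_ohm"
100,140416.575813885,-193498.990343478
118.276595031959,129702.407362214,-172884.716767074
139.893529323539,120128.082512317,-154742.054330175
165.461303153917,111545.166767362,-138821.113245043
195.70199546596,103814.315318567,-124901.385809912
231.469656646736,96802.1518314121,-112786.878806298
273.774428413925,90378.3779523624,-102300.596058113
323.811071996197,84413.557083434,-93277.9808455101
382.992710293586,78778.4033471949,-85559.0522978069
452.990736955868,73345.8762779955,-78979.4134651203
535.782019481577,67997.6982819249,-73361.2795712984
633.704729436275,62636.5335993231,-68507.2278681063
749.524376533712,57203.2198483933,-64200.9926092472
886.511911498592,51694.7671383359,-60219.8178355249
1048.53610347327,46174.6951340476,-56359.5706894199
1240.17280086895,40766.4138527602,-52466.5991145099
1466.83416138027,35626.4235474631,-48463.1742825302
1734.92150084617,30905.3673133055,-44353.2847945866
2052.0060776782,26712.9553969797,-40205.174063705
2427.04291852663,23100.197152521,-36119.5421898303
2870.62372399757,20061.6661325338,-32197.8395116045
3395.27599692394,17550.8937774634,-28521.0031006793
4015.81684109903,15499.2930140371,-25141.0064823784
4749.77142237189,13831.9333812202,-22081.9570281673
5617.8679101825,12477.7539443009,-19345.974225026
6644.62287755692,11374.6803833405,-16920.1696919883
7859.03369228888,10471.2018845852,-14782.7592038332
9295.3974536537,9725.94017391519,-12907.6404419192
10994.279602869,9106.31253557266,-11267.4755694704
13003.6595625666,8586.94580507566,-9835.58693510828
15380.2857601514,8148.17375289963,-8587.01084844991
18191.2783032923,7774.75237105071,-7498.99798073362
21516.0245699216,7454.82218038062,-6551.17198405366
25448.4212475429,7179.09816604065,-5725.48989014658
30099.5261409833,6940.2505278066,-5006.09659344361
35600.6946403093,6732.4372343139,-4379.13024678928
42107.2894282829,6550.95360715884,-3832.5121152965
49803.0681960249,6391.9703787973,-3355.73971915307
58905.3732837025,6252.33782965414,-2939.69307662952
69671.2698108284,6129.43892686459,-2576.45848844674
82404.8056477768,6021.0786698145,-2259.17121185597
97465.5982628938,5925.40016339562,-1981.87667047466
115278.990952879,5840.82044498393,-1739.40897537666
136348.065286264,5765.98095437885,-1527.28514868934
161267.849012546,5699.70890777586,-1341.61333270084
190742.120693319,5640.98684034061,-1179.01330907565
225603.285647807,5588.92831310858,-1036.54776975153
266835.88454445,5542.75831154088,-911.662930378104
315604.398562583,5501.79724932398,-802.137234557756
373286.136390915,5465.44777178619,-706.037049670383
441510.131849528,5433.18375772486,-621.678396278407
522203.150672733,5404.54106763017,-547.593880356721
617644.105765317,5379.10969554406,-482.504110316221
730528.417714807,5356.5270621451,-425.292979545824
864044.138213917,5336.47224606167,-374.98628108608
1021961.98625265,5318.66099462225,-330.7331953813
1208741.83986061,5302.84138838669,-291.790256183981
1429658.69091378,5288.79005884859,-257.50745489053
1690951.62019129,5276.3088778088,-227.316191049256
2e+06,5265.22205165039,-200.718817554429
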