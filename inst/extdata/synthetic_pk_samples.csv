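"animal_id","time_min","activity_bq","plasma_mass_g"
"CBX_01",1,66489,0.0995984843907299
"CBX_01",2,65394.5666666667,0.106492128880377
"CBX_01",3,59542.7333333333,0.102894130358308
"CBX_01",5,54344.2666666667,0.111274846275725
"CBX_01",7.5,35033.8333333333,0.0864849629059843
"CBX_01",10,42722.7333333333,0.123872661577956
"CBX_01",15,29054.4333333333,0.109193215878809
"CBX_01",20,17006.4,0.0761745991531554
"CBX_01",30,15771.4,0.0902411052982329
"CBX_01",40,12921.9333333333,0.0892733437402432
"CBX_01",60,11969.3,0.12041213759579
"CBX_01",90,6735.53333333333,0.113111391702458
"CBX_01",120,3816.36666666667,0.104419030141104
"CBX_01",150,2484.7,0.105797190698721
"CBX_01",180,1446.13333333333,0.096883158714124
"CBX_02",1,43433.3333333333,0.0916325289993389
"CBX_02",2,42705.1333333333,0.0977758549650811
"CBX_02",3,37978.2,0.0925686286163129
"CBX_02",5,32202.6,0.0927005194986247
"CBX_02",7.5,27385.3,0.0952748209628163
"CBX_02",10,23925.1333333333,0.0975162817519107
"CBX_02",15,17341.9333333333,0.0920564047179204
"CBX_02",20,13921.2,0.087345303038006
"CBX_02",30,11035.4,0.0886564642914718
"CBX_02",40,11791.2333333333,0.114619692139905
"CBX_02",60,6234.63333333333,0.0884568528363895
"CBX_02",90,4513.53333333333,0.106955540700367
"CBX_02",120,2368.46666666667,0.0905086282483803
"CBX_02",150,1609.46666666667,0.0970996815091294
"CBX_02",180,1207.43333333333,0.113842748487474
"CBX_03",1,54426.9666666667,0.0860036414863724
"CBX_03",2,53125.9333333333,0.0910074138647279
"CBX_03",3,48756.2,0.0889304848290802
"CBX_03",5,50061.5666666667,0.107786371792347
"CBX_03",7.5,31550.2333333333,0.0820806205943845
"CBX_03",10,26364.4,0.0805093998398237
"CBX_03",15,28687.2333333333,0.113482389052244
"CBX_03",20,17822.3,0.0838804193601096
"CBX_03",30,15232.4333333333,0.0915420277431792
"CBX_03",40,16010.8,0.116485227898364
"CBX_03",60,8027.83333333333,0.0852381293462922
"CBX_03",90,5488.86666666667,0.0976318242952281
"CBX_03",120,3513.13333333333,0.10056066895665
"CBX_03",150,2075,0.0935422827954678
"CBX_03",180,1708.76666666667,0.119685724688906
"MCBX_01",1,25932.0666666667,0.0966898642164536
"MCBX_01",2,17026.0333333333,0.0709937101255794
"MCBX_01",3,19841.6666666667,0.089407442719553
"MCBX_01",5,19412.9,0.102779547379559
"MCBX_01",7.5,17182.4666666667,0.107494859183813
"MCBX_01",10,14549.4,0.102415825366662
"MCBX_01",15,13224.7,0.110061857034628
"MCBX_01",20,10712.3333333333,0.0981485397477699
"MCBX_01",30,8452.03333333333,0.0901817328680901
"MCBX_01",40,7952.3,0.10092907945238
"MCBX_01",60,5506.1,0.0994721560444887
"MCBX_01",90,3091.93333333333,0.0991967210146056
"MCBX_01",120,1720.53333333333,0.0934589633276966
"MCBX_01",150,977.1,0.0904931649092042
"MCBX_01",180,684.033333333333,0.110195617628122
"MCBX_02",1,30936,0.100231832745851
"MCBX_02",2,30835.7666666667,0.111778636025166
"MCBX_02",3,24360.7333333333,0.0954645340032827
"MCBX_02",5,22634.0333333333,0.104159275387056
"MCBX_02",7.5,15894.8,0.0866155760947544
"MCBX_02",10,14267.6666666667,0.087080252615904
"MCBX_02",15,13435.6,0.0969092578596679
"MCBX_02",20,12710.8333333333,0.101565120929557
"MCBX_02",30,9873.86666666667,0.0916608324812883
"MCBX_02",40,9045.93333333333,0.0997545071690534
"MCBX_02",60,5617.06666666667,0.0886264844827398
"MCBX_02",90,3976.23333333333,0.110720542475233
"MCBX_02",120,2621.6,0.123144985817914
"MCBX_02",150,1295.6,0.104229731049957
"MCBX_02",180,712.266666666667,0.0986306095278124
"MCBX_03",1,32541,0.102640159291757
"MCBX_03",2,31893.0666666667,0.112412003930768
"MCBX_03",3,27895.7666666667,0.10643297238832
"MCBX_03",5,20109.2,0.0900323739079742
"MCBX_03",7.5,15124.7,0.0799770154557434
"MCBX_03",10,16001.1333333333,0.095241608930591
"MCBX_03",15,14301.7,0.100441799818969
"MCBX_03",20,11130.4,0.0861886464154825
"MCBX_03",30,11344.0666666667,0.102475196546158
"MCBX_03",40,9538.6,0.102241896503271
"MCBX_03",60,7110.4,0.108614789440003
"MCBX_03",90,3376.23333333333,0.0907323773538928
"MCBX_03",120,2098.7,0.0967955699522127
"MCBX_03",150,1350.46666666667,0.106730247768224
"MCBX_03",180,638.2,0.087343702430164
"CPFPX_01",1,59489.7,0.10947971479479
"CPFPX_01",2,40606.8666666667,0.0839602000964434
"CPFPX_01",3,51675.4333333333,0.113404146150429
"CPFPX_01",5,40417.2,0.102274969760896
"CPFPX_01",7.5,35862.7666666667,0.105022248988996
"CPFPX_01",10,32374.5666666667,0.102709838446406
"CPFPX_01",15,20956.2333333333,0.0741406477592068
"CPFPX_01",20,24496.1666666667,0.0917575818817394
"CPFPX_01",30,24014.1,0.0968819545359952
"CPFPX_01",40,20968.6,0.0934258992256908
"CPFPX_01",60,16979.9,0.102197343160503
"CPFPX_01",90,10999.9333333333,0.110223805679702
"CPFPX_01",120,6085.6,0.103561644659944
"CPFPX_01",150,3978,0.115396055557202
"CPFPX_01",180,2436.7,0.12226972453089
"CPFPX_02",1,41176.1,0.101795691326518
"CPFPX_02",2,37683.3666666667,0.10461218925322
"CPFPX_02",3,32792.3666666667,0.0967603230013761
"CPFPX_02",5,29518.7333333333,0.100519004944617
"CPFPX_02",7.5,23131.9666666667,0.0911483321191716
"CPFPX_02",10,25323.1333333333,0.108178070464903
"CPFPX_02",15,23501.2,0.11155945303687
"CPFPX_02",20,24031.1,0.120614390235178
"CPFPX_02",30,18471.1666666667,0.100225430975591
"CPFPX_02",40,15522.6,0.0931613201368137
"CPFPX_02",60,12705.1,0.102441982449217
"CPFPX_02",90,7098.96666666667,0.09515395305517
"CPFPX_02",120,4413.26666666667,0.100709972710099
"CPFPX_02",150,2858.33333333333,0.111023049436113
"CPFPX_02",180,1371.53333333333,0.0936099594192774
"CPFPX_03",1,31576.3,0.0940484127508249
"CPFPX_03",2,25981.3333333333,0.0870084024756561
"CPFPX_03",3,24560.6,0.0874855761631861
"CPFPX_03",5,22962.2,0.0939430991819948
"CPFPX_03",7.5,21323.7,0.101090319741834
"CPFPX_03",10,22229.8,0.114168322931724
"CPFPX_03",15,18383.1,0.105141191667185
"CPFPX_03",20,18303.2,0.11081613404385
"CPFPX_03",30,16001.6333333333,0.104269336931599
"CPFPX_03",40,13382.7666666667,0.0961661187354733
"CPFPX_03",60,9507.06666666667,0.0927880201525577
"CPFPX_03",90,4950.63333333333,0.0800432428626638
"CPFPX_03",120,3846.46666666667,0.105924526496507
"CPFPX_03",150,1949.03333333333,0.0915584952306683
"CPFPX_03",180,1172.06666666667,0.0954630223586697
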