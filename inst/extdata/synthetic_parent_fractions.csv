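"animal_id","time_min","fraction"
"CBX_01",1,0.975937746722108
"CBX_01",2,0.920201791383162
"CBX_01",3,0.905105510927898
"CBX_01",5,0.818845172543842
"CBX_01",7.5,0.790827572010371
"CBX_01",10,0.69009794773981
"CBX_01",15,0.645911608058725
"CBX_01",20,0.56501794309755
"CBX_01",30,0.506692330810568
"CBX_01",40,0.414907313653751
"CBX_01",60,0.360443593295405
"CBX_01",90,0.311019755335953
"CBX_01",120,0.294011274773261
"CBX_01",150,0.251734048954722
"CBX_01",180,0.242344109791809
"CBX_02",1,0.966049074568332
"CBX_02",2,0.939534963760648
"CBX_02",3,0.891732847216987
"CBX_02",5,0.841022305528641
"CBX_02",7.5,0.762222166410122
"CBX_02",10,0.718893521282344
"CBX_02",15,0.628859589813139
"CBX_02",20,0.577575367966906
"CBX_02",30,0.514714901003647
"CBX_02",40,0.435810306744273
"CBX_02",60,0.379215185304528
"CBX_02",90,0.316576589097361
"CBX_02",120,0.299136867161995
"CBX_02",150,0.232930539677027
"CBX_02",180,0.246109215142237
"CBX_03",1,0.960813963327765
"CBX_03",2,0.952867828751646
"CBX_03",3,0.865959950106096
"CBX_03",5,0.842339738268565
"CBX_03",7.5,0.750263150549796
"CBX_03",10,0.727323101250594
"CBX_03",15,0.621983283225961
"CBX_03",20,0.609597708612275
"CBX_03",30,0.524781253995857
"CBX_03",40,0.439516838506924
"CBX_03",60,0.353631000844359
"CBX_03",90,0.326804095790624
"CBX_03",120,0.286656711464752
"CBX_03",150,0.276258392274318
"CBX_03",180,0.270818124852613
"MCBX_01",1,0.987842562099977
"MCBX_01",2,0.923139590927677
"MCBX_01",3,0.836625594702385
"MCBX_01",5,0.724619246154888
"MCBX_01",7.5,0.646155368379984
"MCBX_01",10,0.527505655229423
"MCBX_01",15,0.421384239555102
"MCBX_01",20,0.381207133554637
"MCBX_01",30,0.274140350097541
"MCBX_01",40,0.246805518640676
"MCBX_01",60,0.179810625407018
"MCBX_01",90,0.128903027056668
"MCBX_01",120,0.147363468837421
"MCBX_01",150,0.166863800326587
"MCBX_01",180,0.149916740431905
"MCBX_02",1,0.984081106230109
"MCBX_02",2,0.934861706784634
"MCBX_02",3,0.845208493906108
"MCBX_02",5,0.738565638076978
"MCBX_02",7.5,0.622634824921454
"MCBX_02",10,0.607748466070714
"MCBX_02",15,0.437858547123756
"MCBX_02",20,0.342416025265208
"MCBX_02",30,0.304367131373993
"MCBX_02",40,0.245028511379793
"MCBX_02",60,0.194340459462835
"MCBX_02",90,0.150642232391868
"MCBX_02",120,0.115647045855622
"MCBX_02",150,0.117918429893906
"MCBX_02",180,0.133824603615095
"MCBX_03",1,1
"MCBX_03",2,0.9383181283779
"MCBX_03",3,0.846416823823649
"MCBX_03",5,0.741254485491137
"MCBX_03",7.5,0.640785906358737
"MCBX_03",10,0.528531901773357
"MCBX_03",15,0.412336787431891
"MCBX_03",20,0.398227804013326
"MCBX_03",30,0.290991927049127
"MCBX_03",40,0.215286901871948
"MCBX_03",60,0.159724961847893
"MCBX_03",90,0.132142700845111
"MCBX_03",120,0.153088235039691
"MCBX_03",150,0.119463611057566
"MCBX_03",180,0.108521790176989
"CPFPX_01",1,0.995371195667882
"CPFPX_01",2,0.926128184539106
"CPFPX_01",3,0.794478652344342
"CPFPX_01",5,0.664287059579744
"CPFPX_01",7.5,0.586233217647213
"CPFPX_01",10,0.481903405104103
"CPFPX_01",15,0.353050270606814
"CPFPX_01",20,0.274305059313966
"CPFPX_01",30,0.221243087583422
"CPFPX_01",40,0.140109812150808
"CPFPX_01",60,0.123835449454213
"CPFPX_01",90,0.0773236530898926
"CPFPX_01",120,0.0881332245452063
"CPFPX_01",150,0.0544582941965195
"CPFPX_01",180,0.0903297477857185
"CPFPX_02",1,0.957588434102717
"CPFPX_02",2,0.935431753002251
"CPFPX_02",3,0.83710612721062
"CPFPX_02",5,0.655093893711819
"CPFPX_02",7.5,0.591492484571375
"CPFPX_02",10,0.472439056568145
"CPFPX_02",15,0.364048182452866
"CPFPX_02",20,0.322645166385381
"CPFPX_02",30,0.227009508016271
"CPFPX_02",40,0.169754563087915
"CPFPX_02",60,0.115449526389532
"CPFPX_02",90,0.0717832350756061
"CPFPX_02",120,0.0747335877462152
"CPFPX_02",150,0.0638240372646367
"CPFPX_02",180,0.0897049800187004
"CPFPX_03",1,1
"CPFPX_03",2,0.883967718822459
"CPFPX_03",3,0.809734260238432
"CPFPX_03",5,0.663032595579857
"CPFPX_03",7.5,0.56515908961553
"CPFPX_03",10,0.489646380599343
"CPFPX_03",15,0.383158633730561
"CPFPX_03",20,0.292351310573701
"CPFPX_03",30,0.211350694408552
"CPFPX_03",40,0.177852541810479
"CPFPX_03",60,0.152660621431883
"CPFPX_03",90,0.0726813006477536
"CPFPX_03",120,0.0704251881008841
"CPFPX_03",150,0.0697812454678176
"CPFPX_03",180,0.0615598725707098
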