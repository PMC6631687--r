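"compound_id","replicate","time_min","remaining_pct"
"CBX",1,0,100
"CBX",1,2,96.1771249859244
"CBX",1,5,88.3759983508581
"CBX",1,10,88.0137809609241
"CBX",1,15,80.6090895700892
"CBX",1,20,84.600586575662
"CBX",2,0,100
"CBX",2,2,96.4220265699821
"CBX",2,5,94.7537726671712
"CBX",2,10,86.0327881714248
"CBX",2,15,77.4910105670367
"CBX",2,20,70.4102006471404
"CBX",3,0,100
"CBX",3,2,89.1187032653596
"CBX",3,5,91.0042534572868
"CBX",3,10,80.4321289739906
"CBX",3,15,73.3107052795724
"CBX",3,20,68.6606809243281
"MCBX",1,0,100
"MCBX",1,2,92.8872586820307
"MCBX",1,5,77.9781988493257
"MCBX",1,10,65.3510817315875
"MCBX",1,15,50.4752138696412
"MCBX",1,20,50.5109863650064
"MCBX",2,0,100
"MCBX",2,2,87.9498571532114
"MCBX",2,5,87.4535630683273
"MCBX",2,10,67.6287903859352
"MCBX",2,15,54.0820547257974
"MCBX",2,20,49.5771161144467
"MCBX",3,0,100
"MCBX",3,2,86.2117438984677
"MCBX",3,5,78.585919512507
"MCBX",3,10,72.6214636748459
"MCBX",3,15,60.6684618970302
"MCBX",3,20,40.1811029663889
"CPFPX",1,0,100
"CPFPX",1,2,95.0046954619581
"CPFPX",1,5,85.5737911045488
"CPFPX",1,10,60.8523365472425
"CPFPX",1,15,48.6864273290167
"CPFPX",1,20,38.9554544235462
"CPFPX",2,0,100
"CPFPX",2,2,90.9978515139246
"CPFPX",2,5,83.5889297648518
"CPFPX",2,10,64.018672834322
"CPFPX",2,15,48.500104909974
"CPFPX",2,20,38.8188377968573
"CPFPX",3,0,100
"CPFPX",3,2,99.5639948481789
"CPFPX",3,5,77.003219827598
"CPFPX",3,10,57.1915974117693
"CPFPX",3,15,49.1454034588627
"CPFPX",3,20,40.2375558148139
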