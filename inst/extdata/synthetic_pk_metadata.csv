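"animal_id","injected_activity_bq","injected_amount_nmol","body_weight_kg"
"CBX_01",20462887.0270705,0.17909270645483,0.475262757225059
"CBX_02",18822788.9128034,0.265374884321968,0.499109890894779
"CBX_03",21162756.1866758,0.405793440654764,0.514740212922529
"MCBX_01",18066635.5686188,0.21050292773737,0.54260624740111
"MCBX_02",24095843.4951471,0.45187465949526,0.511217093961753
"MCBX_03",23724570.962737,0.529094883869259,0.549080441645925
"CPFPX_01",29565041.3718897,0.507279114308255,0.49460813247269
"CPFPX_02",21918469.3635322,0.432227333411503,0.454704377689644
"CPFPX_03",20186970.1335506,0.628544446088641,0.576447785254593
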