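"animal_id","counts_plasma","counts_filtrate","compound_id"
"CBX_uf01",32102,905,"CBX"
"CBX_uf02",30414,751,"CBX"
"CBX_uf03",30383,816,"CBX"
"CBX_uf04",32085,936,"CBX"
"CBX_uf05",31980,883,"CBX"
"CBX_uf06",34474,927,"CBX"
"CBX_uf07",32218,852,"CBX"
"MCBX_uf01",32594,1505,"MCBX"
"MCBX_uf02",34344,1599,"MCBX"
"MCBX_uf03",34289,1444,"MCBX"
"MCBX_uf04",32170,1478,"MCBX"
"MCBX_uf05",34136,1467,"MCBX"
"MCBX_uf06",34007,1573,"MCBX"
"MCBX_uf07",33729,1461,"MCBX"
"CPFPX_uf01",35166,620,"CPFPX"
"CPFPX_uf02",33218,595,"CPFPX"
"CPFPX_uf03",30876,544,"CPFPX"
"CPFPX_uf04",31386,541,"CPFPX"
"CPFPX_uf05",35480,649,"CPFPX"
"CPFPX_uf06",31249,544,"CPFPX"
"CPFPX_uf07",35777,634,"CPFPX"
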