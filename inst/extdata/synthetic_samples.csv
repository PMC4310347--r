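"species","source","treatment","tissue","genotype","area_5mdC","area_dC","percent_mC"
"fam01_sp01","lab","control","leaf","",120,480,NA
"fam01_sp01","lab","control","leaf","",132,470,NA
"fam01_sp01","literature","control","leaf","Col-0",NA,NA,21.5
"fam01_sp01","literature","treated","leaf","Col-0",NA,NA,28
"fam01_sp02","lab","control","leaf","",310,700,NA
"fam01_sp02","lab","control","leaf","",295,720,NA
"fam03_sp01","literature","control","leaf","g1",NA,NA,18.2
"fam03_sp01","literature","control","leaf","g2",NA,NA,19.6
"fam03_sp01","literature","treated","root","g1",NA,NA,30.1
"fam05_sp01","literature","control","leaf","",88,350,NA
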