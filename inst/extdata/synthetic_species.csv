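"species","family","percent_mC","c_value_pg","n_replicates"
"fam01_sp01","fam01",16.79,0.1832,1
"fam01_sp02","fam01",14.487,0.517,1
"fam01_sp03","fam01",23.604,1.6386,1
"fam01_sp04","fam01",13.49,0.6856,1
"fam01_sp05","fam01",12.263,0.2629,1
"fam01_sp06","fam01",20.976,NA,1
"fam01_sp07","fam01",17.113,0.5286,1
"fam01_sp08","fam01",10.932,0.1524,1
"fam02_sp01","fam02",18.796,4.8019,1
"fam02_sp02","fam02",34.73,79.8541,1
"fam02_sp03","fam02",32.243,NA,1
"fam02_sp04","fam02",24.686,5.9659,1
"fam02_sp05","fam02",27.103,NA,1
"fam02_sp06","fam02",34.41,19.1433,1
"fam03_sp01","fam03",16.541,0.6667,1
"fam03_sp02","fam03",21.805,NA,1
"fam03_sp03","fam03",21.948,0.9296,1
"fam03_sp04","fam03",21.289,3.4008,1
"fam03_sp05","fam03",17.446,NA,1
"fam04_sp01","fam04",25.186,11.9162,1
"fam04_sp02","fam04",31.473,NA,1
"fam04_sp03","fam04",23.86,12.9056,1
"fam04_sp04","fam04",21.01,NA,1
"fam05_sp01","fam05",32.587,NA,1
"fam05_sp02","fam05",27.781,6.7223,1
"fam05_sp03","fam05",29.148,37.2354,1
"fam05_sp04","fam05",35.714,41.8854,1
"fam06_sp01","fam06",18.093,1.1831,1
"fam06_sp02","fam06",19.059,2.1663,1
"fam06_sp03","fam06",11.528,NA,1
"fam07_sp01","fam07",25.726,16.5997,1
"fam07_sp02","fam07",35.308,19.4839,1
"fam07_sp03","fam07",23.76,6.4363,1
"fam08_sp01","fam08",26.909,NA,1
"fam08_sp02","fam08",29.649,49.5936,1
"fam09_sp01","fam09",22.673,4.8951,1
"fam09_sp02","fam09",20.7,4.1056,1
"fam10_sp01","fam10",16.042,0.4626,1
"fam10_sp02","fam10",23.122,1.2405,1
"fam11_sp01","fam11",18.756,1.2035,1
"fam12_sp01","fam12",18.854,4.6319,1
"fam13_sp01","fam13",30.701,104.1522,1
"fam14_sp01","fam14",30.519,NA,1
"fam15_sp01","fam15",40,73.456,1
"fam16_sp01","fam16",27.305,6.8786,1
"fam17_sp01","fam17",18.285,1.0502,1
"fam18_sp01","fam18",27.659,5.6294,1
"fam19_sp01","fam19",14.539,1.2095,1
"fam20_sp01","fam20",25.147,5.6693,1
"fam21_sp01","fam21",28.343,18.369,1
"fam22_sp01","fam22",22.777,5.9916,1
"fam23_sp01","fam23",33.767,NA,1
"fam24_sp01","fam24",19.503,1.2358,1
"fam25_sp01","fam25",39.977,26.0791,1
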