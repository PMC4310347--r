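(((fam16_sp01:1,((((fam08_sp02:1,fam08_sp01:1):1,(fam22_sp01:1,(fam07_sp01:1,(fam07_sp02:1,fam07_sp03:1):1):1):1):1,((((fam02_sp06:1,fam02_sp03:1):1,fam02_sp04:1):1,((fam02_sp02:1,fam02_sp05:1):1,fam02_sp01:1):1):1,(((fam04_sp02:1,fam04_sp01:1):1,fam04_sp04:1):1,fam04_sp03:1):1):1):1,(fam25_sp01:1,(fam13_sp01:1,fam23_sp01:1):1):1):1):1,(fam20_sp01:1,(fam18_sp01:1,(((fam03_sp05:1,fam03_sp02:1):1,(fam03_sp01:1,fam03_sp04:1):1):1,fam03_sp03:1):1):1):1):1,(((fam10_sp02:1,fam10_sp01:1):1,((fam19_sp01:1,((fam14_sp01:1,fam15_sp01:1):1,((fam05_sp01:1,((fam05_sp04:1,fam05_sp02:1):1,fam05_sp03:1):1):1,fam21_sp01:1):1):1):1,(((fam11_sp01:1,fam24_sp01:1):1,fam12_sp01:1):1,(fam06_sp01:1,(fam06_sp03:1,fam06_sp02:1):1):1):1):1):1,((fam09_sp02:1,fam09_sp01:1):1,((((fam01_sp08:1,(fam01_sp05:1,(fam01_sp04:1,fam01_sp06:1):1):1):1,(fam01_sp07:1,(fam01_sp01:1,fam01_sp02:1):1):1):1,fam01_sp03:1):1,fam17_sp01:1):1):1):1);
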