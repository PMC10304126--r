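NAME,CLASS,SPEC,N_GENOTYPES
Green1218,green,"DA, FF, and PU (2012-2018), GE (2012, 2014-2018), GF (2012)",12
Green1820,green,"DA, FF, GE, and PU (2018-2020)",9
Yellow1216,yellow,"FF and PU (2012-2016), GE (2012, 2014, 2015), GF (2012)",8
Yellow1720,yellow,"FF and PU (2017-2020), GE (2017)",10
Winter1417,winter,"GF and PU (2014, 2016, 2017), DA (2014, 2017), GE (2014, 2016)",10
Winter1921,winter,"PU (2019-2021), GE and SJ (2019, 2021)",15
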