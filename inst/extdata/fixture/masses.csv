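"chick_id","date","mass_g"
"C0001","2009-06-05",23.2
"C0002","2009-06-05",25.9
"C0002","2009-06-10",51
"C0002","2009-06-17",122.7
"C0003","2009-06-10",18.6
"C0004","2009-06-07",32.8
"C0005","2009-06-03",27.8
"C0005","2009-06-08",57.7
"C0005","2009-06-14",110.8
"C0006","2009-06-07",22.2
"C0007","2009-06-07",16
"C0007","2009-06-13",57.1
"C0007","2009-06-19",126.1
"C0007","2009-06-25",199
"C0008","2009-06-04",19.6
"C0008","2009-06-11",70.9
"C0008","2009-06-17",136.6
"C0008","2009-06-21",182.4
"C0009","2009-06-13",32.5
"C0009","2009-06-19",69.2
"C0009","2009-06-25",121.8
"C0010","2009-06-13",27.3
"C0010","2009-06-20",73.9
"C0011","2009-06-06",25
"C0011","2009-06-13",75.6
"C0011","2009-06-17",115.5
"C0011","2009-06-25",189.9
"C0012","2010-06-03",35
"C0013","2010-06-09",29.9
"C0013","2010-06-16",79.1
"C0013","2010-06-20",115.4
"C0013","2010-06-26",174.8
"C0014","2010-06-10",39.7
"C0014","2010-06-16",67.1
"C0015","2010-06-05",24.4
"C0015","2010-06-12",69.9
"C0015","2010-06-18",139.9
"C0015","2010-06-24",206.2
"C0016","2010-06-05",20.6
"C0016","2010-06-10",51.6
"C0017","2010-06-10",22.4
"C0017","2010-06-15",55.2
"C0018","2010-06-02",29.9
"C0018","2010-06-07",57.9
"C0018","2010-06-14",125.7
"C0018","2010-06-21",189.3
"C0019","2010-06-04",21.9
"C0019","2010-06-10",64.1
"C0019","2010-06-17",133.5
"C0019","2010-06-23",196.7
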