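"chick_id","date","status"
"C0001","2009-06-08","dead"
"C0002","2009-06-08","alive"
"C0002","2009-06-11","alive"
"C0002","2009-06-14","alive"
"C0002","2009-06-17","alive"
"C0002","2009-06-20","alive"
"C0002","2009-06-23","dead"
"C0003","2009-06-13","dead"
"C0004","2009-06-10","dead"
"C0005","2009-06-06","alive"
"C0005","2009-06-09","alive"
"C0005","2009-06-12","alive"
"C0005","2009-06-15","alive"
"C0005","2009-06-18","alive"
"C0005","2009-06-21","dead"
"C0006","2009-06-10","dead"
"C0007","2009-06-10","alive"
"C0007","2009-06-13","alive"
"C0007","2009-06-16","alive"
"C0007","2009-06-19","alive"
"C0007","2009-06-22","alive"
"C0007","2009-06-25","alive"
"C0007","2009-06-28","alive"
"C0008","2009-06-07","alive"
"C0008","2009-06-10","alive"
"C0008","2009-06-13","alive"
"C0008","2009-06-16","alive"
"C0008","2009-06-19","alive"
"C0008","2009-06-22","alive"
"C0008","2009-06-25","alive"
"C0009","2009-06-16","alive"
"C0009","2009-06-19","alive"
"C0009","2009-06-22","alive"
"C0009","2009-06-25","alive"
"C0009","2009-06-28","dead"
"C0010","2009-06-16","alive"
"C0010","2009-06-19","alive"
"C0010","2009-06-22","alive"
"C0010","2009-06-25","dead"
"C0011","2009-06-09","alive"
"C0011","2009-06-12","alive"
"C0011","2009-06-15","alive"
"C0011","2009-06-18","alive"
"C0011","2009-06-21","alive"
"C0011","2009-06-24","alive"
"C0011","2009-06-27","alive"
"C0012","2010-06-06","dead"
"C0013","2010-06-12","alive"
"C0013","2010-06-15","alive"
"C0013","2010-06-18","alive"
"C0013","2010-06-21","alive"
"C0013","2010-06-24","alive"
"C0013","2010-06-27","alive"
"C0013","2010-06-30","alive"
"C0014","2010-06-13","alive"
"C0014","2010-06-16","alive"
"C0014","2010-06-19","dead"
"C0015","2010-06-08","alive"
"C0015","2010-06-11","alive"
"C0015","2010-06-14","alive"
"C0015","2010-06-17","alive"
"C0015","2010-06-20","alive"
"C0015","2010-06-23","alive"
"C0015","2010-06-26","alive"
"C0016","2010-06-08","alive"
"C0016","2010-06-11","alive"
"C0016","2010-06-14","dead"
"C0017","2010-06-13","alive"
"C0017","2010-06-16","alive"
"C0017","2010-06-19","dead"
"C0018","2010-06-05","alive"
"C0018","2010-06-08","alive"
"C0018","2010-06-11","alive"
"C0018","2010-06-14","alive"
"C0018","2010-06-17","alive"
"C0018","2010-06-20","alive"
"C0018","2010-06-23","alive"
"C0019","2010-06-07","alive"
"C0019","2010-06-10","alive"
"C0019","2010-06-13","alive"
"C0019","2010-06-16","alive"
"C0019","2010-06-19","alive"
"C0019","2010-06-22","alive"
"C0019","2010-06-25","alive"
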