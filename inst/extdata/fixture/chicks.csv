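"chick_id","brood_id","plot","hatch_date"
"C0001","B2009_01","South","2009-06-05"
"C0002","B2009_01","South","2009-06-05"
"C0003","B2009_02","North","2009-06-10"
"C0004","B2009_03","South","2009-06-07"
"C0005","B2009_04","North","2009-06-03"
"C0006","B2009_05","South","2009-06-07"
"C0007","B2009_05","South","2009-06-07"
"C0008","B2009_06","North","2009-06-04"
"C0009","B2009_07","South","2009-06-13"
"C0010","B2009_07","South","2009-06-13"
"C0011","B2009_08","North","2009-06-06"
"C0012","B2010_01","South","2010-06-03"
"C0013","B2010_02","North","2010-06-09"
"C0014","B2010_03","South","2010-06-10"
"C0015","B2010_04","North","2010-06-05"
"C0016","B2010_05","South","2010-06-05"
"C0017","B2010_06","North","2010-06-10"
"C0018","B2010_07","South","2010-06-02"
"C0019","B2010_08","North","2010-06-04"
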