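individual_id,province,habitat,age,tissue,d13C,d15N,date
A,P1,coastal,adult,muscle,-20,8,2003-06-15
A,P1,coastal,adult,collagen,-18,10,2003-06-15
B,P1,coastal,adult,muscle,-24,6,2003-06-20
B,P1,coastal,adult,collagen,-24,6,2003-06-20
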