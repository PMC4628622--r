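variant_key	individual_id	genotype
3:134264558:GA:TT	III:1	0/1
3:134264558:GA:TT	III:2	0/0
3:134264558:GA:TT	III:4	0/1
3:134264558:GA:TT	III:5	0/0
3:134264558:GA:TT	III:7	0/1
3:134264558:GA:TT	IV:1	0/1
3:134264558:GA:TT	IV:5	0/1
3:134264558:GA:TT	IV:6	0/0
3:134264558:GA:TT	IV:7	0/1
3:134264558:GA:TT	IV:8	0/0
3:134264558:GA:TT	IV:9	0/1
3:134264558:GA:TT	IV:11	0/0
3:134264558:GA:TT	V:6	0/1
3:134264558:GA:TT	V:7	0/1
3:134264558:GA:TT	V:8	0/1
7:926250:T:G	III:1	0/0
7:926250:T:G	III:2	0/0
7:926250:T:G	III:4	0/0
7:926250:T:G	III:5	0/0
7:926250:T:G	III:7	0/0
7:926250:T:G	IV:1	0/0
7:926250:T:G	IV:5	0/0
7:926250:T:G	IV:6	0/0
7:926250:T:G	IV:7	0/0
7:926250:T:G	IV:8	0/0
7:926250:T:G	IV:9	0/0
7:926250:T:G	IV:11	0/0
7:926250:T:G	V:6	0/0
7:926250:T:G	V:7	0/0
7:926250:T:G	V:8	0/0
11:61560000:C:T	IV:9	0/1
11:61560000:C:T	III:4	0/0
11:61560000:C:T	III:5	0/0
19:32840000:C:G	III:2	0/1
19:32840000:C:G	IV:11	0/1
18:59450000:G:A	IV:6	0/1
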