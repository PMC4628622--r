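FAM_DD	II:1	0	0	1	0	0
FAM_DD	II:2	0	0	2	0	0
FAM_DD	III:1	II:1	II:2	1	2	0
FAM_DD	III:2	0	0	2	1	1
FAM_DD	III:4	II:1	II:2	2	9	0
FAM_DD	III:5	0	0	1	1	0
FAM_DD	III:7	II:1	II:2	2	2	0
FAM_DD	III:8	0	0	1	0	0
FAM_DD	IV:1	III:1	III:2	1	2	1
FAM_DD	IV:5	III:1	III:2	2	2	1
FAM_DD	IV:6	III:1	III:2	2	1	1
FAM_DD	IV:7	III:8	III:7	1	2	1
FAM_DD	IV:8	0	0	2	0	0
FAM_DD	IV:9	III:5	III:4	1	2	1
FAM_DD	IV:11	III:8	III:7	2	1	1
FAM_DD	V:6	IV:7	IV:8	1	2	1
FAM_DD	V:7	IV:7	IV:8	2	2	1
FAM_DD	V:8	IV:7	IV:8	1	2	1
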