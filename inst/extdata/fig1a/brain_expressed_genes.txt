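# brain-expression gene whitelist (worked example; includes synthetic decoys)
CEP63
DNAJC11
GET4
INTS5
PAQR9
RNF152
TNRC18
ZNF507
DECOY1
DECOY2
DECOY3
DECOY4
DECOY5
DECOY6
DECOY7
DECOY8
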