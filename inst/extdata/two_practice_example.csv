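provider_id,group_id,category,proportion,weight
A,g1,poor,0.40,0.5
A,g1,OK,0.10,0.5
A,g1,good,0.50,0.5
B,g1,poor,0.30,0.5
B,g1,OK,0.30,0.5
B,g1,good,0.40,0.5
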