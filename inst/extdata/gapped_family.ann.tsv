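# sequence_id	term_id
gapped.m01	GO:0000003
gapped.m02	GO:0000003
gapped.m03	GO:0000007
gapped.m04	EC:2.7.1.1
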