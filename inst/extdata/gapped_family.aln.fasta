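>gapped.m01
MKVLS-TGWQERIH--PLNDA
>gapped.m02
MKVIS-TGWKERIHAYPLNDA
>gapped.m03
MRVLSQTGWQDRIH--PLNEA
>gapped.m04
MKVLS-SGWQERLH--PINDA
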