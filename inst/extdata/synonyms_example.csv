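raw,canonical
CHONT#1,CHONTE#1
CHONTE#1#1,CHONTE#1
GUL96,GUL-96
RANA96,RANA-96
DOROKHSHAN,DARUKSHAN-08/DORAKSHAN-08
HD 2285,HD2285
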