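[chf]
I50.1
I50.2
[diabetes]
E11.0
E11.2
[copd]
J44.0
J44.8
[renal]
N18.3
N18.4
[arthritis]
M05.9
M06.9
[depression]
F32.0
F32.1
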