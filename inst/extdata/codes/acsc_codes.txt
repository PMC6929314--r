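I10
I50.9
E11.9
J18.9
J44.1
J45.9
N39.0
E10.1
I20.9
J81
L03.9
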