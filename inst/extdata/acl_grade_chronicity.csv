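grade,chronic,acute
III,10,24
II,4,6
I_and_0,3,13
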