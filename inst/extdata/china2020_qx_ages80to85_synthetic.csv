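age,qx
80,0.0350
81,0.0391
82,0.0437
83,0.0488
84,0.0546
85,0.0610
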