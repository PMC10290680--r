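0.91800000000000004,0,0,0,0,0,0,0,0,0,0
0.079000000000000001,0.91800000000000004,0,0,0,0,0,0,0,0,0
0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0,0,0,0,0,0
0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0,0,0,0,0
0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0,0,0,0
0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0,0,0
0,0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0,0
0,0,0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0,0
0,0,0,0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0,0
0,0,0,0,0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004,0
0,0,0,0,0,0,0,0,0.0030000000000000001,0.079000000000000001,0.91800000000000004
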