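from	to
n01_01	g01_01
n01_01	g01_02
n01_02	g01_01
n01_02	g01_02
n01_03	g01_01
n01_03	g01_02
n02_01	g02_01
n02_01	g02_02
n02_02	g02_01
n02_02	g02_02
n02_03	g02_01
n02_03	g02_02
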