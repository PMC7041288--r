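from	to
g01_01	d01_01
g01_01	d01_02
g01_01	d01_03
g01_02	d01_01
g01_02	d01_02
g01_02	d01_03
g01_02	d02_03
g02_01	d02_01
g02_01	d02_02
g02_01	d02_03
g02_02	d02_01
g02_02	d02_02
g02_02	d02_03
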