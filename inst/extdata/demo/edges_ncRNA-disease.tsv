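from	to
n01_01	d01_01
n01_01	d01_02
n01_01	d01_03
n01_01	d02_01
n01_02	d01_01
n01_02	d01_02
n01_02	d01_03
n01_03	d01_03
n02_01	d02_01
n02_01	d02_02
n02_01	d02_03
n02_02	d02_01
n02_02	d02_03
n02_03	d02_01
n02_03	d02_02
n02_03	d02_03
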