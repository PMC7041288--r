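id	expression	family
n01_01	1.1370958447146668	c01
n01_02	0.9435301828603911	c01
n01_03	1.036312841133734	c01
n02_01	2.0539023801893914	c02
n02_02	2.058020632085348	c02
n02_03	1.9342497164845325	c02
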