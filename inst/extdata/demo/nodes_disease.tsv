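id	severity	category
d01_01	0.9937285900947579	c01
d01_02	1.1304869654223486	c01
d01_03	1.2286645392701108	c01
d02_01	2.1314958848978907	c02
d02_02	2.0978167526364278	c01
d02_03	2.0881791226863204	c02
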