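id	activity	pathway
g01_01	0.9185429061729762	c01
g01_02	1.0283957806364306	c02
g02_01	1.982808264424038	c02
g02_02	2.1214674699172598	c02
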