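{"clusters":[{"ncrnas":["n01_01","n01_02","n01_03"],"diseases":["d01_01","d01_02","d01_03"]},{"ncrnas":["n02_01","n02_02","n02_03"],"diseases":["d02_01","d02_02","d02_03"]}],"positive_pairs":[{"ncrna":"n01_01","disease":"d01_01"},{"ncrna":"n01_01","disease":"d01_02"},{"ncrna":"n01_01","disease":"d01_03"},{"ncrna":"n01_01","disease":"d02_01"},{"ncrna":"n01_02","disease":"d01_01"},{"ncrna":"n01_02","disease":"d01_02"},{"ncrna":"n01_02","disease":"d01_03"},{"ncrna":"n01_03","disease":"d01_03"},{"ncrna":"n02_01","disease":"d02_01"},{"ncrna":"n02_01","disease":"d02_02"},{"ncrna":"n02_01","disease":"d02_03"},{"ncrna":"n02_02","disease":"d02_01"},{"ncrna":"n02_02","disease":"d02_03"},{"ncrna":"n02_03","disease":"d02_01"},{"ncrna":"n02_03","disease":"d02_02"},{"ncrna":"n02_03","disease":"d02_03"}]}
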