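pathway_id	enzyme
threonine	thrA
threonine	thrB
threonine	thrC
lysine	lysC
lysine	asd
lysine	dapA
lysine	dapB
lysine	lysA
methionine	metA
methionine	metB
methionine	metC
methionine	metE
arginine	argA
arginine	argB
arginine	argC
arginine	argD
arginine	argE
arginine	argG
arginine	argH
histidine	hisG
histidine	hisB
histidine	hisC
histidine	hisD
tryptophan	trpA
tryptophan	trpB
tryptophan	trpC
tryptophan	trpD
tryptophan	trpE
leucine	leuA
leucine	leuB
leucine	leuC
leucine	leuD
proline	proA
proline	proB
proline	proC
serine	serA
serine	serB
serine	serC
cysteine	cysE
cysteine	cysK
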