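annotator	index	label	surface
A	1	ApparatusAction	to a 25 ml three-necked round-bottomed flask fitted with a dean-stark trap, a condenser, and a nitrogen inlet/outlet and magnetic stirrer
A	2	ApparatusAction	was subsequently sealed with a rubber septum
A	3	Stir	stirring the reaction mixture overnight at room temperature
A	4	Concentrate	evaporation of the eluate
A	5	Yield	afforded 8 as a white solid (2.63 g, 57% yield)
B	1	ApparatusAction	a 25 ml three-necked round-bottomed flask fitted with a dean-stark trap, a condenser, and a nitrogen inlet/outlet
B	2	ApparatusAction	which was subsequently sealed with a rubber septum
B	3	Stir	after stirring the reaction mixture overnight at room temperature
B	4	Yield	which then afforded 8 as a white solid (2.63 g, 57% yield)
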