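name	formula	class
PC(32:0)	C40H80NO8P	PC
PC(34:3)	C42H78NO8P	PC
PC(30:0)	C38H76NO8P	PC
PC(32:1)	C40H78NO8P	PC
PC(34:1)	C42H82NO8P	PC
PC(34:2)	C42H80NO8P	PC
PC(36:2)	C44H84NO8P	PC
PC(36:4)	C44H80NO8P	PC
PC(38:4)	C46H84NO8P	PC
PC(38:6)	C46H80NO8P	PC
TG(48:5)	C51H88O6	TG
TG(50:6)	C53H90O6	TG
TG(46:2)	C49H90O6	TG
TG(48:2)	C51H94O6	TG
TG(50:1)	C53H100O6	TG
TG(50:3)	C53H96O6	TG
TG(52:2)	C55H102O6	TG
TG(52:4)	C55H98O6	TG
TG(54:4)	C57H102O6	TG
TG(54:6)	C57H98O6	TG
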