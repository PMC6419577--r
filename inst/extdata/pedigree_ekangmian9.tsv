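child	parent1	parent2	role
Lone Star			exotic_founder
Deltapine 15			exotic_founder
Stoneville 2B			exotic_founder
Guannong 1			exotic_founder
52-128			exotic_founder
Jinyu 3	Guannong 1	Lone Star	backbone
Jin 3-34-3	Jinyu 3		backbone
Jinmian 2	Jin 3-34-3	Deltapine 15	backbone
Ejing 1	Jinmian 2	52-128	backbone
Xuzhou 209	Deltapine 15		backbone
Shanmian 7	Stoneville 2B	52-128	backbone
Zhong 7263	Xuzhou 209	Shanmian 7	backbone
CCRI4	Deltapine 15	Stoneville 2B	backbone
Shan 5012	Lone Star	Stoneville 2B	backbone
MO-3	CCRI4	Shan 5012	backbone
EJ1xZ7263	Ejing 1	Zhong 7263	hybrid
Ekangmian 9	EJ1xZ7263	MO-3	backbone
Zhongmian 12	CCRI4		backbone
Emian 6	Ejing 1	Shanmian 7	backbone
Jingzhou 47	Jinmian 2		backbone
Zhong 309	Ekangmian 9	Zhong 7263	elite
Zhong 053	Ekangmian 9	Emian 6	elite
Zhong 392326	Ekangmian 9	Zhongmian 12	elite
9053	Ekangmian 9		elite
Zhong 9018	Ekangmian 9	Jingzhou 47	elite
1638	Ekangmian 9	MO-3	elite
ZhongCJ 377126	Ekangmian 9	Ejing 1	elite
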