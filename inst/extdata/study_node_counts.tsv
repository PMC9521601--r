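subject	channel	node_count	node_relevance
teacher	FP2-AF8	5	21
teacher	FP1-AF7	3	13
teacher	AF3-F5	3	13
teacher	CP6-TP8	2	8
teacher	P4-P6	2	8
teacher	C6-CP6	2	8
teacher	P8-P6	2	8
teacher	CP4-CP6	1	4
teacher	C4-CP4	1	4
teacher	AF8-F6	1	4
teacher	CP6-P6	1	4
teacher	AF7-F5	1	4
teacher	C4-C6	0	0
teacher	AF4-F6	0	0
teacher	TP8-P8	0	0
teacher	CP4-P4	0	0
teacher	FP2-AF4	0	0
teacher	FP1-AF3	0	0
child	CP4-CP6	7	29
child	C4-C6	4	17
child	CP6-TP8	3	13
child	FP1-AF7	2	8
child	AF4-F6	2	8
child	TP8-P8	2	8
child	C4-CP4	1	4
child	CP4-P4	1	4
child	FP2-AF4	1	4
child	FP1-AF3	1	4
child	FP2-AF8	0	0
child	AF3-F5	0	0
child	P4-P6	0	0
child	C6-CP6	0	0
child	AF8-F6	0	0
child	CP6-P6	0	0
child	P8-P6	0	0
child	AF7-F5	0	0
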