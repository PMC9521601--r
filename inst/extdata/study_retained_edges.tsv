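dyad	teacher_channel	child_channel	bin
dyad2	FP1-AF7	CP4-CP6	0.2-0.25
dyad2	AF3-F5	TP8-P8	0.2-0.25
dyad2	P8-P6	C4-CP4	0.2-0.25
dyad3	P4-P6	AF4-F6	0.2-0.25
dyad3	AF7-F5	CP4-CP6	0.2-0.25
dyad3	CP6-TP8	CP6-TP8	0.2-0.25
dyad3	FP2-AF8	TP8-P8	0.2-0.25
dyad3	FP2-AF8	CP4-CP6	0.25-0.3
dyad3	AF8-F6	CP6-TP8	0.25-0.3
dyad3	FP1-AF7	CP4-CP6	0.25-0.3
dyad4	AF3-F5	CP4-CP6	0.2-0.25
dyad4	CP6-TP8	CP6-TP8	0.2-0.25
dyad4	P8-P6	C4-C6	0.2-0.25
dyad4	AF3-F5	CP4-P4	0.2-0.25
dyad4	FP1-AF7	CP4-CP6	0.2-0.25
dyad4	FP2-AF8	CP4-CP6	0.2-0.25
dyad4	P4-P6	C4-C6	0.25-0.3
dyad4	C4-CP4	AF4-F6	0.25-0.3
dyad4	CP4-CP6	C4-C6	>0.3
dyad4	CP6-P6	C4-C6	>0.3
dyad5	FP2-AF8	FP1-AF7	0.2-0.25
dyad5	C6-CP6	FP1-AF7	0.2-0.25
dyad5	FP2-AF8	FP2-AF4	0.2-0.25
dyad5	C6-CP6	FP1-AF3	0.2-0.25
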