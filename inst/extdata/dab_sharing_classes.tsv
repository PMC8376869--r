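lineage	membership	n
DAB1	bream	4
DAB1	roach	10
DAB1	hybrid	0
DAB1	bream+hybrid	1
DAB1	hybrid+roach	5
DAB1	bream+roach	0
DAB1	bream+hybrid+roach	1
DAB3	bream	14
DAB3	roach	31
DAB3	hybrid	16
DAB3	bream+hybrid	5
DAB3	hybrid+roach	13
DAB3	bream+roach	0
DAB3	bream+hybrid+roach	5
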