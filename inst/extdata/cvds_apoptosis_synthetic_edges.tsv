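# Synthetic illustrative apoptosis-centred CVD subnetwork: signed edges.
source_id	target_id	effect
FASR	FADD	activation
TNFR1	TRADD	activation
TRADD	TRAF2	activation
TRAF2	ASK1	activation
ASK1	JNK1	activation
JNK1	P53	activation
P53	BAX	activation
BCL2	CYCS	inhibition
BAX	CYCS	activation
CYCS	APAF1	activation
APAF1	CASP9	activation
CASP9	CASP3	activation
FADD	CASP8	activation
CASP8	CASP3	activation
CASP3	PARP1	activation
TRADD	NFKB1	activation
NFKB1	IAP1	activation
IAP1	CASP3	inhibition
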