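# Synthetic illustrative apoptosis-centred CVD subnetwork: node table.
# Constructed for this package; not a transcription of any curated database.
node_id	compartment	position
FASR	plasma_membrane	upstream
TNFR1	plasma_membrane	upstream
TRADD	cytoplasm	upstream
FADD	cytoplasm	upstream
TRAF2	cytoplasm	upstream
ASK1	cytoplasm	upstream
JNK1	cytoplasm	downstream
P53	nucleus	downstream
BAX	cytoplasm	downstream
BCL2	cytoplasm	downstream
CYCS	cytoplasm	downstream
APAF1	cytoplasm	downstream
CASP9	cytoplasm	downstream
CASP3	cytoplasm	downstream
CASP8	cytoplasm	downstream
PARP1	nucleus	downstream
NFKB1	nucleus	downstream
IAP1	cytoplasm	downstream
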