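# Synthetic illustrative vascular endothelial cell contraction (VECC)
# CVD subnetwork: node table. Constructed for this package.
node_id	compartment	position
REN	blood	upstream
ACE	blood	upstream
AGTR1	plasma_membrane	upstream
ADRB1	plasma_membrane	upstream
ECE1	plasma_membrane	upstream
EDNRA	plasma_membrane	upstream
CACNA1C	plasma_membrane	upstream
NOS3	cytoplasm	upstream
PLCB1	cytoplasm	downstream
IP3R	cytoplasm	downstream
CAM	cytoplasm	downstream
MYLK	cytoplasm	downstream
MYL9	cytoplasm	downstream
PRKC	cytoplasm	downstream
ROCK1	cytoplasm	downstream
ACTA2	cytoplasm	downstream
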