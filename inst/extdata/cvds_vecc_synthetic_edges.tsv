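# Synthetic illustrative VECC CVD subnetwork: signed edges.
source_id	target_id	effect
REN	ACE	activation
ACE	AGTR1	activation
AGTR1	PLCB1	activation
ADRB1	PLCB1	activation
ECE1	EDNRA	activation
EDNRA	PLCB1	activation
PLCB1	IP3R	activation
IP3R	CAM	activation
CACNA1C	CAM	activation
CAM	MYLK	activation
NOS3	MYLK	inhibition
MYLK	MYL9	activation
AGTR1	PRKC	activation
PRKC	ROCK1	activation
ROCK1	MYL9	activation
MYL9	ACTA2	activation
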