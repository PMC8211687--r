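axis	ligand	receptor	category
NECTIN2-TIGIT	NECTIN2	TIGIT	co-inhibitory
PVR-TIGIT	PVR	TIGIT	co-inhibitory
PDL1-PD1	CD274	PDCD1	co-inhibitory
PDL2-PD1	PDCD1LG2	PDCD1	co-inhibitory
CD86-CTLA4	CD86	CTLA4	co-inhibitory
CD80-CTLA4	CD80	CTLA4	co-inhibitory
LGALS9-HAVCR2	LGALS9	HAVCR2	co-inhibitory
CD86-CD28	CD86	CD28	co-stimulatory
CD80-CD28	CD80	CD28	co-stimulatory
ICOSLG-ICOS	ICOSLG	ICOS	co-stimulatory
TNFSF4-TNFRSF4	TNFSF4	TNFRSF4	co-stimulatory
CD70-CD27	CD70	CD27	co-stimulatory
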