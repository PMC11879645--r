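symbol	cell_class
GABRA1	neuron
GABRA2	neuron
GRIA1	neuron
GRIA2	neuron
GRIN1	neuron
GRIN2A	neuron
GRIN2B	neuron
GRM5	neuron
MAP2	neuron
AQP4	glia
GFAP	glia
MBP	glia
MOG	glia
OLIG1	glia
OLIG2	glia
S100B	glia
SOX9	glia
SOX10	glia
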