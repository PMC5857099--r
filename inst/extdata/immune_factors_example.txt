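# Example immune-factor gene list (synthetic convenience fixture).
# Real analyses should supply their own curated list; markers below are
# common myeloid/immunosuppression-axis genes used for demonstration only.
CD163
MRC1
CSF1R
CCL2
CCL22
IL10
ARG1
NOS2
CD274
FOXP3
IL6
TGFB1
CXCL8
S100A8
S100A9
ITGAM
CD33
IL17D
STAT3
VEGFA
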