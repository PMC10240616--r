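# Macrophage polarization transcriptional regulatory network.
# RECONSTRUCTED rule set: the update rules below were rebuilt from the
# published description of the network (29 nodes, 60 interactions;
# 14 transcription factors, 15 extracellular components) and the signalling
# mechanisms stated in its accompanying text, and calibrated against the
# published dose-response thresholds. They are not a verbatim copy of the
# original supplementary rule list. See the package vignette for the audit
# trail of each mechanism.
#
# Format: <name>, <klass>, <rule-or-dash>
#
# -- extracellular components (clamp-only inputs) --
IFNG, extracellular, -
IFNB, extracellular, -
TNFAe, extracellular, -
IL1B, extracellular, -
IL6e, extracellular, -
IL4e, extracellular, -
IL13e, extracellular, -
IL10e, extracellular, -
IgG, extracellular, -
GCGCR, extracellular, -
MCSF, extracellular, -
TGFB, extracellular, -
A2a, extracellular, -
Hypoxia, extracellular, -
LPS, extracellular, -
#
# -- transcription factors --
STAT1, transcription_factor, (IFNG OR IFNB) AND NOT (SOCS1 OR TGFB OR PPARG OR KLF4)
STAT6, transcription_factor, (IL4e OR IL13e OR TGFB OR IRF4 OR A2a) AND NOT (STAT1 OR SOCS3)
STAT3, transcription_factor, (IL10e OR MCSF OR (IL6e AND IL10e)) AND NOT SOCS3
NFkB, transcription_factor, (TNFAe OR IL1B OR IL6e OR LPS OR AP1) AND NOT (SOCS1 OR STAT3 OR SMAD23 OR KLF4)
AP1, transcription_factor, NFkB OR (PI3K AND IL6e)
ERK, transcription_factor, IgG OR (IgG AND GCGCR) OR (AP1 AND IL1B)
SOCS1, transcription_factor, STAT6 OR IRF4
SOCS3, transcription_factor, NFkB
HIF1a, transcription_factor, (Hypoxia OR TGFB OR A2a OR MCSF OR (LPS AND A2a)) AND NOT STAT1
SMAD23, transcription_factor, TGFB AND NOT ERK
PI3K, transcription_factor, IL6e OR MCSF OR IgG OR A2a
PPARG, transcription_factor, (IL4e OR IL13e OR IRF4) AND NOT NFkB
KLF4, transcription_factor, (STAT6 OR IL10e OR IRF4) AND NOT NFkB
IRF4, transcription_factor, (IL4e OR MCSF OR IL13e) AND NOT STAT1
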