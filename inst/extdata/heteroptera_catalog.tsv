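# Heteropteran mitochondrial gene-order catalog: every distinct rearranged
# arrangement reported for true bugs, with the families and species counts
# carrying it, plus one aggregated record for the species retaining the
# insect ancestral ground pattern.
#
# Transcription conventions:
# * Gene orders are FULL circular orders: published excerpts showing only the
#   rearranged region are embedded in the ancestral background (the unprinted
#   remainder of the circle is ancestral). "//" marks an unsequenced region;
#   genes falling inside such a region are simply not listed.
# * "~" = minority strand. No inversion is known in Heteroptera, so every
#   gene keeps its ancestral strand.
# * "[X]" = gene confirmed absent from the genome; "[X?]" = absence
#   unresolved (the gene may instead lie in an unsequenced region). The
#   source table marks absent genes typographically; for the four loss
#   records whose lost gene the plain-text rendering cannot show, the
#   assignment used here is: Nabis ferus = trnI (stated in the source text),
#   Phymata americana = trnI (shared with Nabis ferus), Nabidae sp. 2 = trnM,
#   Urostylididae = trnQ, Pachynomidae = trnC. Ischnobaenella hainana trnY is
#   recorded unresolved ([trnY?]): it may be lost or may sit in the
#   unsequenced region between trnV and trnI.
# * Bare serine/leucine tRNA letters are disambiguated by ancestral position:
#   the block-B "S" (trnA-R-N-S-E-F cluster) is trnS1, the CYTB-adjacent "S"
#   is trnS2, the ND1-adjacent "L" is trnL1, the COI-adjacent "L" is trnL2.
# * One arrangement shared verbatim across families is one record with
#   "/"-separated families and per-family species counts.
# * The two Nabidae records print identically in the source table but carry
#   different losses (see above); they are deliberately NOT merged.
taxon	infraorder	family	species_count	gene_order	synapomorphy
Enicocephalomorpha C1 group	Enicocephalomorpha	Aenictopecheidae/Enicocephalidae	1/4	CR-~rrnL-~trnV-~rrnS-~ND1-~trnL1-~trnP-trnT-ND6-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-CYTB-trnS2	infraorder
Stenopirates sp.	Enicocephalomorpha	Enicocephalidae	1	CR-~rrnL-~trnV-~rrnS-~ND1-~trnL1-~trnP-trnT-ND6-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnE-trnR-trnN-trnS1-~trnF-//-~ND4L-CYTB-trnS2	none
Ceratocombus spp.	Dipsocoromorpha	Ceratocombidae	2	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnE-trnN-trnS1-trnR-~trnF-//-~rrnL-~rrnS-~trnV	genus
Gerridae trnF-duplication group	Gerromorpha	Gerridae	5	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	genus
Nabis ferus	Cimicomorpha	Nabidae	1	CR-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS-[trnI]	none
Nabidae sp. 2	Cimicomorpha	Nabidae	1	CR-trnI-~trnQ-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS-[trnM]	none
Pachynomidae sp.	Cimicomorpha	Pachynomidae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnY-//-trnR-trnA-trnN-trnS1-trnE-~trnF-//-CYTB-trnS2-~trnH-~ND1-~trnL1-~rrnL-~trnV-~rrnS-[trnC]	none
Reduviidae trnI-duplication sp.	Cimicomorpha	Reduviidae	1	CR-~trnQ-trnI-trnI-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Ptilocnemus lemur	Cimicomorpha	Reduviidae	1	CR-trnI-trnW-~trnQ-trnM-ND2-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Ischnobaenella hainana	Cimicomorpha	Reduviidae	1	CR-~trnV-//-trnI-~trnQ-trnM-ND2-trnW-~trnC-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~rrnS-[trnY?]	none
Phymata americana	Cimicomorpha	Reduviidae	1	CR-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS-[trnI]	none
Reduviidae trnR-duplication sp.	Cimicomorpha	Reduviidae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnR-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Reduviidae R-A-translocation sp.	Cimicomorpha	Reduviidae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnR-trnA-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Reduviidae trnT-tandem-duplication sp.	Cimicomorpha	Reduviidae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Reduviidae trnT-dispersed-duplication sp.	Cimicomorpha	Reduviidae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-trnT-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Aradidae A1 group	Pentatomomorpha	Aradidae	5	CR-~trnQ-trnI-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	family
Aradidae Calisiinae sp.	Pentatomomorpha	Aradidae	1	CR-~trnQ-trnI-trnM-ND2-~trnC-trnW-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Aradidae Aradinae sp.	Pentatomomorpha	Aradidae	1	CR-~trnQ-trnI-~trnC-~trnY-trnM-ND2-trnW-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Pyrrhocoroidea C6 group	Pentatomomorpha	Largidae/Pyrrhocoridae	4/12	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-~trnP-trnT-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	superfamily
Pyrrhocoridae trnT-hexaplication sp.	Pentatomomorpha	Pyrrhocoridae	1	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-~trnP-trnT-trnT-trnT-trnT-trnT-trnT-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
Urostylididae sp.	Pentatomomorpha	Urostylididae	1	CR-trnI-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS-[trnQ]	none
Heteroptera ground pattern	various	various	372	CR-trnI-~trnQ-trnM-ND2-trnW-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS	none
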