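# bbxkit cis-element library, version 1
# Named plant cis-regulatory elements with IUPAC consensus strings and the
# three functional categories used in BBX promoter profiling. Consensi are
# literal/IUPAC approximations of the commonly cited core motifs; the
# scanning and aggregation machinery, not any particular consensus, is the
# contract of this module.
name	consensus	category	function_note
Skn-1-motif	GTCAT	development	endosperm expression
GCN4_motif	TGAGTCA	development	endosperm expression
CAT-box	GCCACT	development	meristem expression
CCGTCC-box	CCGTCC	development	meristem expression
O2-site	GATGAYRTGR	development	zein metabolism regulation
MRE	AACCTAA	development	light responsiveness (MYB binding)
Box 4	ATTAAT	development	light responsiveness
circadian	CAANNNNATC	development	circadian control
TGACG-motif	TGACG	hormone	MeJA responsiveness
ABRE	ACGTG	hormone	ABA responsiveness
TGA-element	AACGAC	hormone	auxin responsiveness
AuxRR-core	GGTCCAT	hormone	auxin responsiveness
GARE-motif	TCTGTTG	hormone	gibberellin responsiveness
P-box	CCTTTTG	hormone	gibberellin responsiveness
TATC-box	TATCCCA	hormone	gibberellin responsiveness
ERE	ATTTCAAA	hormone	ethylene responsiveness
ARE	AAACCA	stress	anaerobic induction
Box-W1	TTGACC	stress	fungal elicitor responsiveness
HSE	AAAAAATTTC	stress	heat stress responsiveness
TC-rich repeats	GTTTTCTTAC	stress	defense and stress responsiveness
GC-motif	CCCCCG	stress	anoxia-specific inducibility
MBS	CAACTG	stress	drought inducibility (MYB binding)
LTR	CCGAAA	stress	low-temperature responsiveness
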