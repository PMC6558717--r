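# bbxkit domain pattern library, version 1
# Anchor-and-spacer consensus patterns for the three BBX-family domains.
# anchors: comma-separated residue classes (alternatives separated by "/")
# gaps:    comma-separated spacer ranges between consecutive anchors ("min-max")
# min_anchor_frac: fraction of anchors that must match (1 = all; the long CCT
#   consensus tolerates 20% anchor mismatches because real CCT domains deviate)
# B-BOX domains are anchored on their conserved Cys/His zinc-binding scaffold;
# the B-BOX1 form is the canonical C-C-C-C/H-H-H scaffold with the gap ranges
# below, the B-BOX2 form is C-X2-4-H-X7-10-C-X1-4-D/C-X4-7-C-X2-C-X3-6-H-X2-5-H.
# The CCT consensus is R-X5-R-Y-X-E-K-X3-R-X3-K-X2-R-Y-X2-R-K-X2-A-X2-R-X-R-X-K-G-R-F-X-K.
name	anchors	gaps	min_anchor_frac
BBOX1	C,C,C,C/H,H,H	2-4,6-8,2-4,3-4,5-10	1
BBOX2	C,H,C,D/C,C,C,H,H	2-4,7-10,1-4,4-7,2-2,3-6,2-5	1
CCT	R,R,Y,E,K,R,K,R,Y,R,K,A,R,R,K,G,R,F,K	5-5,0-0,1-1,0-0,3-3,3-3,2-2,0-0,2-2,0-0,2-2,2-2,1-1,1-1,0-0,0-0,0-0,1-1	0.8
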