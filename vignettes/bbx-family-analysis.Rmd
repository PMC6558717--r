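---
title: "Methods: comparative BBX gene-family analysis with bbxkit"
author: "bbxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative BBX gene-family analysis with bbxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

B-BOX (BBX) proteins are plant zinc-finger transcription factors defined by
one or two B-BOX domains — Cys/His scaffolds coordinating Zn ions — and, in
part of the family, a C-terminal CCT domain linked to photoperiodic
regulation of flowering. Across plant genomes the family splits into five
clades by domain architecture: double B-BOX plus CCT (clades I and II),
single B-BOX plus CCT (III), double B-BOX without CCT (IV), and single
B-BOX without CCT (V). `bbxkit` implements the complete comparative
analysis of such a family across two genomes — exemplified by the orchids
*Dendrobium officinale* (19 BBX genes) and *Phalaenopsis equestris* (16) —
as a tested, reusable pipeline: domain detection and clade assignment,
ortholog/paralog detection, Ka/Ks selection analysis with sliding windows,
domain-architecture evolution on a phylogeny, promoter cis-element
profiling, and FPKM / qRT-PCR expression quantification. Seeded
synthetic-genome generators emulate every input with recorded ground
truth, so the whole pipeline runs and is validated without any genome
download.

# Domain detection and clade assignment

Domains are found by anchor-and-spacer consensus matching rather than
profile HMMs. A pattern is an ordered list of anchor residue classes with
bounded spacers; the shipped library
(`inst/extdata/domain_patterns.tsv`) encodes:

* **B-BOX2**: `C-X2-4-H-X7-10-C-X1-4-D/C-X4-7-C-X2-C-X3-6-H-X2-5-H`.
* **B-BOX1**: the same Cys/His scaffold canonicalized as anchors
  `C, C, C, C/H, H, H` with spacers `2-4, 6-8, 2-4, 3-4, 5-10`. The
  commonly printed form of this consensus is typographically inconsistent
  (it interleaves extra `X` runs that cannot all be spacers), so the
  canonical form above — which preserves the five-cysteine scaffold with
  four absolutely conserved positions — is fixed in the pattern file and
  is the package's definition.
* **CCT**: the 42-residue consensus
  `R-X5-R-Y-X-E-K-X3-R-X3-K-X2-R-Y-X2-R-K-X2-A-X2-R-X-R-X-K-G-R-F-X-K`,
  matched as a rigid template requiring at least 80% of its 19 anchors
  (`min_anchor_frac`, a configurable knob). Real CCT domains deviate from
  the consensus; exact matching would reject them.

B-BOX patterns require every anchor and are compiled to regular
expressions, which gives leftmost-greedy matching: the spec'd "earliest
start wins, then longest" overlap resolution falls out of the engine.
Cross-pattern overlaps on one protein are resolved by the same greedy
rule, with library order as the final tie-break, so outputs are
deterministic.

Architecture codes list domains N→C; the clade rule table is total:
two B-BOX + CCT → I or II, one B-BOX + CCT → III, two B-BOX → IV, one
B-BOX → V, no B-BOX → excluded from the family. Architecture alone
cannot separate clade I from II (they differ by B-BOX2 sequence
divergence, not composition); `classify_clade()` takes an optional
phylogenetic placement and otherwise defaults to II with an
`architecture_only` flag, II being the ancestral double-B-BOX + CCT
state in the family's trajectory model.

Molecular weights use ExPASy-style average residue masses plus one
water (strict additivity is a tested invariant). Isoelectric points are
found by bisection of the Henderson–Hasselbalch net-charge function on
pH 0–14 to 1e-4, with the Bjellqvist/ExPASy pKa set: side chains D 4.05,
E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0; C-terminus 3.55;
N-terminal pKa depending on the first residue (7.5 default). Note that
this polypeptide convention intentionally differs from free-amino-acid
textbook pKas: glycine as a *peptide* evaluates to pI 5.53 here, not the
free-glycine 5.97.

# Homology by reciprocal best hits

OrthoMCL-style clustering is replaced by reciprocal best hits (RBH) over
global Needleman–Wunsch alignments (BLOSUM62, gap open 10, gap extend
0.5, via `Biostrings::pairwiseAlignment`). At gene-family scale (tens of
proteins) RBH recovers the same pair structure as Markov clustering and
is fully self-contained. Orthologs are cross-genome RBH; paralogs are
within-genome RBH excluding self-hits. Tied best-hit scores reject the
query rather than picking arbitrarily.

Two thresholds gate every reported pair: **identity**, defined as
identical columns divided by the full alignment length (gaps included),
at least 0.3; and **coverage**, substituted columns divided by the
shorter sequence length, at least 0.5. The gaps-included identity
denominator matters: under affine gap costs the aligner excises
unalignable regions, so identity over substituted columns alone sits
near 0.3 even for unrelated family members that merely share domain
anchors, which would make the floor meaningless.

# Ka/Ks: Nei–Gojobori (1986) with Jukes–Cantor correction

The protein alignment of a pair is back-translated into a codon
alignment (each residue its codon, each gap a `---` triplet; trailing
stop codons removed first). Sites per codon follow NG86: each of the
nine single-nucleotide mutations contributes its synonymous fraction,
with mutations to stop codons removed from the per-position denominator
so `syn + nonsyn = 3` exactly. Differences per aligned codon pair are
averaged over all minimal mutational pathways, excluding pathways
through stop codons; a column whose every pathway crosses a stop is
skipped. Both tables are precomputed for all 61 sense codons (and
61×61 pairs) and verified in the test suite against an independent
exhaustive enumeration.

With `S`, `N` the site sums averaged over the two sequences and
`Sd`, `Nd` the summed differences,

$$p_s = S_d / S,\quad p_n = N_d / N,\qquad
d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}p\right)$$

gives `Ks = d(ps)` and `Ka = d(pn)`; `p >= 3/4` is reported as saturated
(`NA`, flagged). Gapped or ambiguous codon columns are skipped in both
global and windowed counts; window coordinates live in alignment space.

Sliding windows use the family-analysis convention of **150 bp windows
advanced by 9 bp** (50 codons, 3-codon steps), giving
`floor((L-150)/9) + 1` windows; alignments shorter than one window
return a single flagged whole-length window.

Selection classes bin the ratio as below 0.3 (strong purifying), 0.3–1
inclusive of both bounds (relaxed purifying), and strictly above 1
(positive); whether the source convention included the endpoints cannot
be determined from its wording, so both-inclusive is fixed and
documented here. Duplication ages classify Ks into a whole-genome
duplication band of `[0.8, 1.6]` — covering the shared orchid WGD near
Ks 1, and chosen so the published paralog values 1.0658 and 1.4562
fall inside while 0.0433 and 0.0827 classify as recent (below 0.2);
both bounds are configuration, not constants.

# Phylogeny and the domain-architecture trajectory

Distances between aligned proteins are Poisson-corrected,
`d = -ln(1 - p)` with `p` the mismatch fraction over shared non-gap
columns (p-distance available by option; Poisson is the default because
branch lengths then approximate substitutions per site). Trees come
from an implemented Saitou–Nei neighbor joining with the Q criterion,
deterministic lexicographic tie-breaking, non-negative branch-length
clamping, and closed-form three-point lengths at the final join; on
additive matrices topology and branch lengths are recovered exactly (a
tested invariant, cross-checked against `ape::nj`). Bootstrap supports
resample alignment columns with replacement (default 1000 replicates,
seeded) and annotate internal nodes with bipartition percentages.

Architectures map to three binary characters — `has_B1_duplicated`
(clade I's B-BOX1 duplication), `has_B2`, `has_CCT` — so clades encode
as I = 111, II = 011, III = 001, IV = 010, V = 000. Ancestral states
come from two-pass Fitch parsimony on a rooted tree; ties resolve
toward the ancestral single-B-BOX state (all zeros), the polarity under
which the earliest BBX proteins carried one B-BOX domain. Rooting is
configurable (the source analyses do not state their rooting beyond
that polarity). Each parent→child flip is a named event: `has_B2` gain
= B-BOX duplication, loss = B-BOX2 deletion; `has_CCT` gain = CCT gain;
`has_B1_duplicated` gain = B-BOX1 duplication. On the clade-shaped tree
`(V,(IV,(II,(III,I))))` the reconstruction yields exactly the four
canonical events of the family's evolutionary model.

# Promoters and cis-elements

Promoters are the 1500 bp immediately 5' of the translation start
(the annotated ATG, not the transcript start), strand-corrected,
truncated with a flag at scaffold edges. The element library
(`inst/extdata/cis_element_library.tsv`) carries 23 named plant
cis-elements in three categories (development, hormone, stress) as
literal/IUPAC consensi; the upstream database's matrices are not
published, so the library is a versioned approximation and the
package's claims attach to the scanning and aggregation machinery, not
to any particular consensus. All (possibly overlapping) matches count;
both strands are scanned by default; promoter `N`s never match in
strict mode (a permissive IUPAC-compatibility mode is available).
Aggregation produces the gene × motif grid, per-category sums, and
within-category ratios that sum to one.

# Expression and qRT-PCR

FPKM values bin into left-closed intervals `[0,1)` not expressed,
`[1,6.8)` low, `[6.8,17.5)` mid-low, `[17.5,44.7)` mid-high,
`[44.7,∞)` high. The verbal A/B/C tissue-group definitions are
formalized (and exposed as configuration) as: A if the median FPKM
across tissues is at least 6.8; B if FPKM is below 1 in at least 7 of
8 tissues; C otherwise. Venn regions over up to six tissues use a
1 FPKM expression threshold.

Relative expression uses 2^−ΔΔCt — with one reference gene and one
control sample it is the only standard estimator consistent with
"relative expression level"; efficiency correction (Pfaffl) is not
modeled. Per replicate ΔCt = Ct_target − Ct_reference; ΔΔCt is the
treated minus control mean; significance stars come from a two-sided
Welch t-test on replicate ΔCt values (n = 3; the source does not name
its test, and with three replicates the t-test is the conventional
choice). The control is the shared untreated sample at the first
timepoint; a per-timepoint control option exists because the source
wording is ambiguous on this point. A lone "97 h" timepoint in the
source narrative is read as a typo for 96 h and not modeled.

# The synthetic-data generators

`sim_config()` fixes the study conditions; its defaults mirror the
family's cardinalities: 19 + 16 genes in clades I–V at 3/3/6/17/6, 13
ortholog plus 2 + 2 paralog pairs, exon counts 1–7 distributed
8/10/7/6/2/2 (counting annotated exon features as-is, since whether
published exon counts include UTR exons is unstated), 1500 bp
promoters, 5/8/6 expression groups over eight tissues, four treatments
× four timepoints × three replicates with Ct noise sd 0.2, ortholog
identity 0.70 at Ks 1.0, paralog identities 0.80/0.95 at Ks pairs
spanning WGD-aged and recent duplicates.

Exactness is engineered, not hoped for: protein backgrounds exclude
Cys and His so the B-BOX scaffold can only match at planted positions
(and pattern realizations are constrained so a planted B-BOX2 can
never double-match the B-BOX1 pattern); promoter planting repairs the
sequence base-by-base until scanned counts equal the planted
expectation on both strands; FPKM groups draw from bands that cannot
cross the classification thresholds. Homolog partners are derived by a
seeded synonymous substitution process at the target Ks plus
single-nucleotide nonsynonymous neighbor substitutions outside the
planted domains down to the target identity, so both identity and Ks
are controlled. `evolve_pair()` is the clean two-lineage process
(Poisson event counts at the target per-site rates, uniform rejection
placement, no stop codons) used for estimator-recovery simulations.

What the generators do *not* emulate: insertions and deletions (all
homologs are colinear), codon-usage and GC biases, rate heterogeneity
along the sequence, UTRs and alternative isoforms, read-level RNA-seq
noise, and real promoter base composition. Passing recovery tests
therefore demonstrates correctness of the machinery under controlled
conditions, not performance on real genomes — in particular RBH on
real proteomes faces domain shuffling and gene loss the toy families
exclude.

# Numerical choices and problem sizes

Deterministic tie-breaks everywhere: greedy leftmost-longest domain
resolution, lexicographic NJ pair selection, best-hit ties rejecting
the query, Fitch ties resolving toward the ancestral state. All
randomness flows from a single integer seed per generator call.

The validation suite sizes its simulations to be decisive yet quick:
Ks recovery uses 1000-codon pairs, 50 replicates per target
(0.1/0.5/1.0, mean within 10% of truth); window localization uses
300-codon chimeras with a 150 bp Ka/Ks = 2 segment, requiring the
top-ratio window's center inside the segment ± 2 steps; the qPCR
scale check averages five independently seeded tables against the
1200–2400 recovery band for the planted 1700-fold induction (a single
table sits only ~2σ from the band edge at Ct noise 0.2, so a one-draw
assertion would fail a few percent of seeds by chance); NJ and Fitch
are checked exactly against brute-force enumeration up to 8 taxa.

# Known limitations

Pattern scanning is not HMM scoring: diverged real BBX domains that an
HMM would accept can fall outside the consensus gap ranges. RBH yields
one-to-one pairs only; many-to-many ortholog groups are out of scope.
NG86 is unweighted (no transition/transversion or codon-frequency
correction) and the ML codon models are deliberately not implemented.
The NJ tree is a family-scale tool, not a replacement for genome-scale
ML phylogenies. Cis-element counts on real promoters depend on the
exact consensus strings, which are approximations here.
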