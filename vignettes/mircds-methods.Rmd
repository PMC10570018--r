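---
title: "Methods: duplex prediction, MRE classification and hybrid-read profiling"
author: "mircds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex prediction, MRE classification and hybrid-read profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircds)
```

## Scope and model

`mircds` implements the computational side of studying microRNA
targeting within protein-coding regions (CDS). Reporter mutagenesis of
miRNA-response elements (MREs) shows that repression through CDS sites
is canonical and stringent: it requires a perfectly paired seed
(miRNA nt 2–8), is strongest when pairing is contiguous across the
seed-plus-cleavage region (nt 2–12, licensing AGO2-mediated slicing),
tolerates a central bulge of one nucleotide, is severely weakened by a
two-nucleotide bulge and abolished by larger ones, and does *not*
strictly require pairing of the three 3′-terminal nucleotides so long
as the overall interface carries few mismatches. The package encodes
this taxonomy as an explicit, configurable rule set and surrounds it
with the machinery needed to apply it at scale: a duplex folder, a
transcriptome scanner, a CLASH/CLEAR-CLIP hybrid-read pipeline and a
ground-truthed simulator.

All coordinates are 0-based half-open on 5′→3′ RNA; BED input stays
0-based and any 1-based table dialect is converted at the boundary.
DNA FASTA is transliterated T→U on read. Minus-strand models and
fragments are reverse-complemented so pairing is always computed in
mRNA orientation.

## Duplex prediction

`predict_duplex()` finds the maximum-score non-crossing antiparallel
intermolecular pairing between a miRNA and a target window by dynamic
programming — hybridization only, with no intramolecular structure, no
partition function and no temperature dependence. The scoring model is
deliberately self-contained and dimensionless:

* pair weights G:C = 3, A:U = 2, G:U = 1 (wobble pairs count, as
  thermodynamic duplex folders do; set `gu = 0` to forbid them);
* helices must contain at least 2 consecutive pairs (isolated pairs
  are never reported);
* an interior loop or bulge between two helices costs
  `gap_open + gap_extend * g`, where `g` is the total number of
  enclosed unpaired nucleotides on both strands; dangling ends are
  free. The defaults (`gap_open = 4`, `gap_extend = 1`) are chosen so
  that a lone two-pair helix cannot pay for a long detour: a genuine
  supplementary helix (≥ 8 pairs in these data) always recoups the
  penalty of a small central bulge, while spurious two-pair helices
  far from the main duplex are rejected.

Ties are broken deterministically: more paired miRNA bases first, then
the 5′-most paired target base. The dynamic program is exact; the test
suite proves it equal to an exhaustive enumeration of every valid
pairing on all 2-mer pairs and hundreds of random instances up to
length 8. A note on a tempting but false invariant: mutating a paired
target base to a non-complementary base does *not* always lower the
optimal score, because in RNA every base has some partner (A:U, C:G,
G:C/U, U:A/G) and the substituted base may recruit a different miRNA
position in a re-alignment. What does hold — and what the tests
assert — is that an optimum of the mutant that leaves the mutated
position unpaired can never beat the original optimum.

An adapter (`duplex_from_dot_bracket()`) ingests two-part
`query&target` dot-bracket strings with an attached free energy from
an external nearest-neighbour duplex folder; downstream code consumes
only the pairing map, so the two scoring modes are interchangeable
there, but they are never mixed in one run.

## Zone profiles and the MRE rule set

`zone_profile()` reduces a pairing map to the quantities the reporter
data discriminate: seed pairing (nt 2–8, contiguous on both strands —
a single-nucleotide target-side bulge inside the seed counts as a seed
imperfection, since even minor seed imperfections abolished
repression), contiguous 2–12 pairing, the central bulge (unpaired
miRNA nt within 9–12 plus target-side insertions bounded by pairs in
9–12), pairing in the supplementary region and of the three
3′-terminal nucleotides, and mismatch totals. The supplementary zone
is nt 12–17; the classifier reports but does not branch on it.
miRNAs shorter than 17 nt get a truncated supplementary zone and are
flagged.

`classify()` maps a profile to `SLICING` > `REPRESSIVE` > `WEAK` >
`NONFUNCTIONAL`. Because the underlying data are a dose-response, the
thresholds live in a `mre_rules()` object: interface-mismatch budget
outside nt 2–12 (default 3; the genome-wide scan's strict setting is
2), the WEAK bulge size (2) and the dead bulge size (3), and an
optional requirement for 3′-terminal pairing, which demotes SLICING
calls to REPRESSIVE rather than rejecting them — so enabling it can
only lower ranks (tested). G:U in the seed counts as paired by
default (`seed_gu = FALSE` to tighten); the reporter series did not
dissect wobble seeds.

The packaged fixture (`reporter_models_path()`) transcribes the
reporter binding models into abstract pairing patterns (lengths,
unpaired positions, target insertions). Since the constructs are known
only through their described properties — seed mismatched or not,
"two bases mismatched at the 3′ end", bulge sizes, a 23-nt variant
keeping 8 of 9 3′-half pairs — the patterns encode those properties
directly; the "seed paired but 3′ end unpaired" construct is encoded
with three unpaired terminal bases, the largest 3′ disruption that the
observed repression permits under the mismatch budget. One documented
anomaly is intentionally *not* modelled: a modest repression observed
for one NOTCH2 interaction despite a seed bulge; the classifier calls
such duplexes NONFUNCTIONAL by design.

## Transcriptome scanning

`scan_transcript()` searches for extensively complementary sites by
exact string matching of the reverse complement of the anchor (nt
2–12; no wobble inside the anchor, as "full complementarity" demands)
followed by gapless antiparallel extension across the full miRNA and a
mismatch budget on the rest of the interface (G:U outside the anchor
counts as a match by default; flaggable). Bulged candidates are
deliberately not enumerated here — that is the duplex module's job —
and sites overhanging the transcript end are discarded because their
pairing is undefined. Sites overlapping a 3′UTR are labelled UTR3 by
the same priority rule the hybrid pipeline uses. Expression filtering
of the miRNA universe is an allowlist input, not recomputed.

A consequence worth stating explicitly: a site whose central region is
bulged (the REPRESSIVE archetype) breaks the mandatory 2–12 anchor and
is therefore invisible to this scanner *by construction*. Recovery
simulations for the scanner accordingly implant anchor-compatible
(SLICING-class) sites; bulged templates are exercised through the
duplex and classifier route instead.

`scan_transcriptome()` runs one permissive pass and derives the count
table across mismatch budgets × the 3′-terminal toggle by filtering,
so monotonicity in the budget and under relaxation of the terminal
requirement holds structurally. The scanner is validated against an
all-windows oracle that re-tests every window of ~100 kb of synthetic
transcriptome by direct per-position comparison.

## Hybrid-read pipeline

The CLASH/CLEAR-CLIP stages compose as: interval expansion (±3 nt, to
compensate nuclease nibbling of fragment ends) → duplicate collapsing →
region annotation → per-hybrid duplex calls. Expansion precedes
collapsing so that "identical target intervals" is evaluated on the
compensated intervals; the methods that inspired the pipeline list the
steps without fixing this order, and collapsing after expansion makes
the criterion deterministic. Region labels take the union of overlap
flags over all overlapping transcripts and resolve by priority: 3′UTR
if any 3′UTR is touched, else CDS for exonic reads outside UTRs, else
5′UTR, else intron; intergenic reads are discarded but accounted.
Pairing profiles (`pairing_matrices()`) stack per-hybrid miRNA pairing
vectors anchored at the 5′ end (aligning seeds) or the 3′ end
(aligning termini) into count-weighted matrices; the two anchorings
carry identical per-read information related by a `width − L` shift,
which is tested exactly. Weighting by duplicate count is the default,
with an unweighted toggle.

## The simulator and what passing tests mean

`simulate_transcriptome()` generates i.i.d. background sequence at a
configurable GC content, structures each transcript as
5′UTR/CDS/3′UTR with the CDS forced divisible by 3, writes the reverse
complement of template-mutated miRNAs into chosen regions at
non-overlapping positions, and lays each transcript on its own
chromosome as two exons around an intron, a configurable fraction on
the minus strand. Implant templates (perfect, central bulges of
1/2/4, seed-only, seed-mismatched-with-3′-pairing, 2/3-nt terminal
mismatches) mirror the reporter constructs; each template's expected
class is derived by classifying its idealised pattern, so generator
truth and classifier semantics cannot drift apart. Mutated positions
receive bases that pair neither Watson–Crick nor wobble, making
template faithfulness exact. `simulate_hybrid_reads()` derives
chimeric reads covering each implant with up to `max_nibble` (3) nt
truncated independently per end — matching the pipeline's +3
compensation — duplicates each read geometrically, and places decoy
reads uniformly within regions drawn from a multinomial mix, avoiding
implants. Everything is deterministic given the seed.

The generator deliberately omits codon structure, RNA secondary
structure and accessibility (a hairpin context is known to reduce
efficacy in reporter data), sequencing error, and miRNA abundance.
Passing recovery tests therefore demonstrate correctness of the
*pipeline arithmetic* — interval bookkeeping, annotation priority,
duplex calling, count conservation — on data with the declared
statistical structure, not performance on real CLIP libraries.

## Validation sizes and numerical choices

The shipped tests and the acceptance script use: exhaustive duplex
enumeration on all 2-mer pairs plus 500 random instances up to length
8; scanner-oracle equality over ~100 kb × 10 miRNAs at budgets 2 and 3;
site recovery over ten seeded replicates of 100 kb with 10 implants
each (sensitivity and decoy count reported); region-fraction recovery
at 5,000 decoy reads (±0.03, about four standard errors of the
multinomial); seed-pairing recovery over ≥1,000 implant-derived
chimeras; and exact shift equivalence of the anchored matrices. These
sizes keep the whole suite within a few minutes on one core while
leaving each comparison statistically meaningful.

Degenerate inputs are handled explicitly: windows shorter than 4 nt
and non-RNA characters are errors; empty regions scan to empty
results; empty region classes give empty matrices; malformed hybrid
rows are dropped with a warning rather than aborting a run; unknown
miRNA names are flagged and excluded from matrices; and
`thickStart == thickEnd` BED12 records become non-coding models with
an empty CDS.

## Limitations

Absolute hybridization energies are out of scope — the internal score
is dimensionless and external ΔG values are only carried, never
computed — so no energy-threshold classification is offered.
Conservation scoring, target-site accessibility, context features and
repression-magnitude regression are likewise out of scope. The
hybrid-table column schema of processed public datasets varies; the
`hybrid_dialect()` mechanism must be configured by the user to match a
given file.
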