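---
title: "Profiling late embryogenesis abundant protein families from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling late embryogenesis abundant protein families from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaprofiler)
```

# Scope and model

Late embryogenesis abundant proteins (LEAPs) are hydrophilic,
largely disordered proteins that accumulate in maturing seeds and in the
vegetative tissues of desiccation-tolerant ("resurrection") plants, where
they are thought to shield proteins and membranes as water is lost. This
package implements the sequence-level part of a LEAP characterisation
study: given protein sequences and Pfam-style domain annotations it

* classifies proteins into the seven classical LEA families (LEA1--LEA5,
  dehydrins, seed maturation proteins) and into motif-architecture
  subgroups,
* computes per-protein physicochemical profiles (GRAVY, pI, molecular
  weight, residue-category composition, the hydrophilin criterion),
* scans for 28 family consensus motifs and the dehydrin K/Y/S segments,
* analyses amphipathicity on the helical wheel (HeliQuest conventions),
* scores hydroxyl-radical scavenging ability (HRSA) additively from
  per-residue rates, and
* filters and summarises differential-expression tables from a
  desiccated-vs-hydrated contrast.

Everything upstream of these steps — sequencing, assembly, BLAST/HMM
annotation, and the external structure/disorder/localisation predictors —
is out of scope; their outputs are consumed as plain tables.

# Classification

Family assignment is a fixed accession map (`map_domain_to_family()`):
PF03760 = LEA1, PF03168 = LEA2, PF03242 = LEA3, PF02987 = LEA4,
PF00477 = LEA5, PF00257 = dehydrin, PF04927 = SMP. The source family
table prints the dehydrin and SMP accessions the other way around, while
its surrounding text repeatedly uses the canonical pairing (PF00257 is
the Pfam *Dehydrin* domain); we treat the printed rows as transposed and
keep the map overridable. Proteins shorter than 100 residues are removed
first; among annotations passing the e-value threshold (default
`1e-5`) the lowest e-value wins, with ties broken by map order — the
multi-domain case is not specified upstream, so a deterministic rule is
chosen and documented.

Subgroups come from motif presence (`assign_subgroup()`), evaluated
most-specific-first so the "extended" LEA2.1 set (M2.1, M2.2, M2.6 plus
M2.3 and M2.5) wins over LEA2.2, and the DEH1-determining M6.3 wins over
the shared dehydrin motifs. When no rule fires, the label is
`<family>.0`, a convention the source material itself uses. For SMPs the
published narrative places an M7.1-only representative in SMP2 and an
M7.1+M7.2 representative in SMP3, so the default map is: M7.2 only
→ SMP1, M7.1 only → SMP2, both → SMP3. This deliberately deviates from a
plausible alternative (M7.1-only → SMP1) because the worked examples in
the text pin down the two subgroups above; the rule table is data, so a
user can swap it. LEA5 is never subdivided — no subdivision is defined
for it — and keeps its family label when any LEA5 motif is present.

# Physicochemical profiling

**GRAVY** is the arithmetic mean of Kyte–Doolittle hydropathies. The
scale choice is validated, not assumed: of the 28 printed consensus-motif
GRAVY values, 25 are reproduced to ±0.001 under Kyte–Doolittle (and under
no other common scale we tried). The three exceptions are instructive:
the M4.3 and M4.4 printed values are evidently transposed (each
recomputes to the other's consensus, to 0.001), and M4.1 prints −1.617
against a recomputed −1.510, suggesting it was computed on a variant
consensus. The registry stores printed values verbatim in
`gravy_printed` and never force-fits them.

**Molecular weight** is the ProtParam convention: average residue masses
plus one water (18.0153 Da), in kDa. **pI** solves the
Henderson–Hasselbalch net-charge curve (termini plus D, E, C, Y, H, K, R
side chains, Bjellqvist pK set) by bisection on pH 0–14; the curve is
monotone decreasing so the root is unique. Because ProtParam's N-terminal
pK depends on the first residue, pI is composition-determined only up to
the N-terminal residue identity. Bisection runs to 0.001 pH internally
and is tested against an independent 1e-4-step grid scan to within 0.01.

**Residue categories** default to charged = {D,E,K,R},
polar = {S,T,N,Q,C,H,Y}, nonpolar = {G,A,V,L,I,P,M,F,W},
aromatic = {F,W,Y,H}. The charged set is validated against a printed
worked count (20 charged of 50 residues on the M1.1 consensus, which
requires His *not* to count as charged). The full partition behind the
published category table is not stated — its rows sum past 100%,
implying overlapping sets — so the scheme is configurable and the
default overlap (His, aromatics) is documented rather than hidden.

**Hydrophilins** are flagged when Gly % > 6 *and* GRAVY < −1.0, both
strict. The source text prints "GRAVY < 1", but under that reading
nearly every LEAP qualifies, contradicting the same text's statement
that only the dehydrin-type proteins qualify; −1.0 is the default and
the printed bound remains available as `gravy_max = 1`.

**Ambiguity codes**: B, Z, U, O are rejected unless explicitly mapped to
X (`allow_ambiguous = TRUE`); X then contributes nothing to any scored
quantity and is excluded from composition denominators. Silent
mis-scoring of translated ORFs is worse than a visible flag.

# Motif scanning and dehydrin segments

The published motif set came from MEME, whose position weight matrices
are not printed; only consensus strings are. Scanning therefore scores
each window by per-position identity against the (possibly degenerate)
consensus pattern, with threshold 0.8 by default and exact matching
available for tests. Hits are selected greedily left-to-right without
overlap, ties by higher identity. Patterns use bracket notation:
`[MF]` is a choice, `[_N]` one optional position.

Dehydrin segments follow the published grammars literally:
K = `KKG[_N][MF]M[DE]KIKEK`, Y = `DEYGNP`, S = maximal merged runs of
SGSSSSSSS / TGSSSSSS / S×7 / S×8. Literalness matters: the M6.4
consensus contains K-segment-like text but lacks the `KKG` prefix, so
the strict grammar does not fire on it — the tests assert the grammar's
behaviour, not a biological judgement.

# Helical wheels

Residue *i* of a window sits at angle (i−1)·100° (the canonical α-helix
step; configurable for 3–10 helices). The hydrophobic moment is the
Eisenberg vector sum divided by window length, on the Fauchère–Pliska
scale (HeliQuest's choice); the transmembrane-candidate scan instead uses
Kyte–Doolittle so its 1.6 threshold keeps its usual meaning. Faces are
maximal contiguous arcs, in wheel order, of hydrophobic residues
({A,V,L,I,M,F,W,C}), of {K,R}, and of {D,E}; a window with all three is
an "A-type" helix. Net charge counts K and R as +1, D and E as −1 and
His as 0, which reproduces a printed worked example (+3 from four Lys,
one Arg, one Glu, one Asp). Window means used for greedy candidate
ordering are rounded to 9 decimals so windows of identical composition
compare as exact ties regardless of summation order.

The transmembrane scan is a deliberate heuristic stand-in: real topology
prediction (TMHMM and kin) is out of scope, and the scan's only claim is
"~19 consecutive strongly hydrophobic residues".

# HRSA

The HRSA score is additive over residues (sum by default — the published
dataset-level scores grow with protein length — with a mean mode
provided). The measured per-residue rate constants were published
elsewhere and are not reprinted, so the shipped table is *ordinal only*:
tier values 9..1 encoding the printed rank order
Trp > Phe,Leu > Ile > His > Arg > Val > Lys,Tyr,Pro > Gln,Thr,Ser >
Glu,Ala,Gly,Asn,Asp. Met and Cys are absent from that order; the default
places these strongly HO•-reactive sulfur residues in the top tier as a
labelled placeholder, unconstrained by `validate_rank_order()`.
Consequently the package's absolute HRSA numbers are not comparable to
the published range (3.9–113.7); only order statements survive the
ordinal encoding, and a measured table can be supplied for quantitative
work.

# Differential expression

`filter_degs()` applies FDR < 0.05 and |log2FC| > 2, both strict. The
source states 0.05 beside its headline results and 0.005 in its methods;
0.05 is the default and both are plain arguments. The packaged 88-row
transcription of the published DEG table reproduces the printed summary
exactly (76% up / 24% down, six DEH1 plus one DEH2 upregulated, no
downregulated genes in LEA1, LEA2.1, LEA5, dehydrin or SMP groups). Two
printed rows sit at or below the stated threshold (one at 1.99, one at
exactly −2.00); the fixture preserves them verbatim and the filter drops
them, so filtering the fixture yields 86 rows — documented, not
corrected. Report percentages round half-up to integers.

# The synthetic world

`generate_proteome()` emulates exactly what the pipeline measures, no
more:

* per-family counts default to the published sizes (24, 127, 18, 96, 11,
  25, 17; total 318);
* lengths are truncated normal with the published per-family means and
  spreads recovered as SE·√n from the published summary table;
* each member embeds its family's consensus motifs (architectures chosen
  so the truth subgroup is defined: LEA1.1, LEA2.2, LEA3.1, LEA4.2,
  LEA5, DEH1, SMP3) at random non-overlapping positions, placed jointly
  by allocating the background slack across gaps so placement never
  deadlocks;
* background residues are i.i.d. from a family composition built by
  exponentially tilting a base composition (a 2:1 blend of the family's
  own motif composition with the all-motif average) until the whole
  protein's *expected* GRAVY — motifs included, at the expected
  truncated-normal length — hits the family target from the published
  summary (e.g. −1.40 for dehydrins);
* every record gets its family's Pfam accession at e-value 1e-10.

A generated dehydrin set of n = 200 recovers mean GRAVY within ±0.15 of
−1.40; classification recovers 100% of true families because the
annotations are clean by construction. That is precisely what a green
test establishes — the machinery, not the biology: the generator has no
positional structure beyond the embedded motifs, no annotation noise, no
length/composition correlation, and no paralogue structure, so
dataset-level published numbers (family summary values, the HRSA range,
hydrophilin counts) are *targets of the stated world*, not reproductions
of the real proteome.

The DEG generator draws up genes as |N(5,2)|+2, down as −(|N(2,1)|+2)
and null as N(0,0.5), with FDR uniform on [0,0.01] for non-null and
[0,1] for null rows; fractions are applied by count rounding so 0.76/0.24
on 88 genes gives exactly 67 and 21.

All randomness flows through one seeded R RNG; outputs record the seed.

# Numerical choices, degeneracies, limitations

* GRAVY/identity/percentage report rounding follows the source's
  conventions (3 decimals for GRAVY, 1 for pI/Mw/percents); internal
  computation is full precision.
* Motif-scan ties (equal identity at one start) prefer the shorter
  variant of an optional-position pattern; greedy selection is ordered
  by start, then identity.
* Empty inputs: zero-row proteome sets flow through every table function;
  `write_fasta()` refuses an empty set; a DEG table with a log2fc of
  exactly 0 counts in neither direction and warns.
* Families with one member report SE = NA and are excluded from the
  Tukey post hoc; with no between-family variance all families share a
  letter. The compact letter display is a small insert-and-absorb
  routine (no CLD package is available in this environment) driven by
  `stats::TukeyHSD` p-values.
* The package never attempts secondary-structure, disorder or
  localisation prediction, phylogenetics, or motif discovery.

# A worked example

```{r example, eval = FALSE}
library(leaprofiler)
gp <- generate_proteome(counts = c(DEH = 10, LEA4 = 10), seed = 1)
cls <- classify_proteome(gp$set, gp$annotations)
table(cls$subgroup)
#>   DEH1 LEA4.2
#>     10     10

prof <- physchem_table(gp$set)
round(mean(prof$gravy[cls$family == "DEH"]), 2)
#> [1] -1.37

detect_dehydrin_segments(gp$set$sequence[1])[, c("kind", "matched_text")]
#>   kind matched_text
#> 1    K  KKGMMDKIKEK
#> 2    Y       DEYGNP
#> 3    S    SGSSSSSSS
```

The `analysis/` scripts run the same machinery at full scale (318
proteins) and write their tables under `results/`; `scripts/acceptance.R`
repeats the end-to-end run headlessly under a caller-supplied seed.
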