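# leaprofiler

Sequence-based characterisation of late embryogenesis abundant (LEA)
protein families.

LEA proteins are hydrophilic, largely intrinsically disordered proteins
that accumulate during seed maturation and in the vegetative tissues of
desiccation-tolerant plants, where they are thought to stabilise
proteins and membranes during extreme water loss. `leaprofiler` is an R
package plus a small analysis workflow for characterising a LEA
proteome from its sequences and domain annotations:

* **Classification** — Pfam accession → family (LEA1–LEA5, dehydrins,
  SMPs) with a ≥ 100 aa length filter and an e ≤ 10⁻⁵ domain threshold;
  motif architecture → subgroup (e.g. LEA1.1 = M1.1 + M1.2,
  DEH1 ⇐ M6.3).
* **Physicochemical profiles** — GRAVY (Kyte–Doolittle mean hydropathy,
  GRAVY = (1/N)·Σ h(rᵢ)), ProtParam-style molecular weight and
  isoelectric point (Bjellqvist pK set, bisection on the
  Henderson–Hasselbalch charge curve), residue-category percentages, and
  the hydrophilin criterion (Gly % > 6 and GRAVY < −1).
* **Motifs and dehydrin segments** — a registry of 28 family consensus
  motifs scanned by per-position identity (threshold 0.8), and the
  literal K/Y/S dehydrin grammars
  (K = `KKG[_N][MF]M[DE]KIKEK`, Y = `DEYGNP`, S = serine-run patterns).
* **Amphipathicity** — HeliQuest-style helical wheels: 11-residue
  windows at 100°/residue, Eisenberg hydrophobic moment
  μH = |Σ h(rₙ)·e^(inδ)|/N on the Fauchère–Pliska scale, hydrophobic /
  positive / negative face segmentation and the A-type flag, plus a
  heuristic hydropathy scan for transmembrane-helix candidates.
* **HRSA** — additive hydroxyl-radical scavenging score from a
  per-residue rate table; the shipped default encodes only the published
  rank order (Trp > Phe,Leu > … > Asp) as ordinal tiers and is labelled
  non-quantitative.
* **Differential expression** — strict FDR < 0.05 and |log2FC| > 2
  filtering and per-subgroup direction summaries, with the published
  88-gene desiccated-vs-hydrated table packaged as a fixture.
* **Synthetic data** — a seeded generator that emulates the published
  dataset shape (seven families totalling 318 proteins, family-specific
  composition hitting the published GRAVY targets, embedded consensus
  motifs, clean annotations, DEG tables with a 76/24 direction split),
  so the entire pipeline is testable offline.

## Worked example

```r
library(leaprofiler)

gp  <- generate_proteome(seed = 42)          # 318 proteins, 7 families
cls <- classify_proteome(gp$set, gp$annotations)
table(cls$family)
#>  DEH LEA1 LEA2 LEA3 LEA4 LEA5  SMP
#>   25   24  127   18   96   11   17

prof <- physchem_table(gp$set)
fs   <- family_summary(cls, prof)
fs$gravy
#>      family   n    mean     se group
#> DEH     DEH  25 -1.4239 0.0248     a
#> LEA1   LEA1  24 -0.8994 0.0314     b
#> LEA2   LEA2 127 -0.0593 0.0117     c
#> LEA3   LEA3  18 -0.6110 0.0498     d
#> LEA4   LEA4  96 -1.0063 0.0187     b
#> LEA5   LEA5  11 -1.0389 0.0512     b
#> SMP     SMP  17 -0.2731 0.0414     e
```

Per-family mean GRAVY recovers the generator's targets (dehydrins most
hydrophilic near −1.40, LEA2 near zero, SMP mildly hydrophilic); `se` is
the standard error and `group` the Tukey-HSD compact letters — families
sharing a letter are not significantly different at α = 0.05.

```r
s <- summarize_degs(table4_degs())   # packaged published DEG table
c(s$total, s$pct_up, s$pct_down)
#> [1] 88 76 24
```

The `analysis/` directory holds the same pipeline as five numbered
narrative scripts (simulate → classify → physchem → motifs/helix/HRSA →
DEG), each writing its tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Rebuilds the synthetic 318-protein proteome under the given seed, runs
the installed package end-to-end (classification, profiles, motif and
segment scans, helix analysis, HRSA, DEG summary), verifies the
printed-table checkpoints, and writes the JSON report to `--out`.
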